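#' Normative reference population summary
#'
#' Mean and standard deviation of demographic and CT-densitometric
#' characteristics of the 100-subject normative adult cohort (53 male,
#' 47 female) that anchors the package's reference values, reported for the
#' whole cohort and per sex. These summaries parameterize the synthetic
#' cohort generator and serve as published anchors for consistency checks
#' (e.g. gas volume + lung weight at 1 g/ml reproduces total lung volume).
#'
#' @return A data.frame with columns `variable`, `group`
#'   (`all`/`male`/`female`), `mean` and `sd`.
#' @examples
#' ref <- reference_population()
#' subset(ref, variable == "lung_weight_g")
#' @export
reference_population <- function() {
  row <- function(variable, all_m, all_s, m_m, m_s, f_m, f_s)
    data.frame(variable = variable,
               group = c("all", "male", "female"),
               mean = c(all_m, m_m, f_m),
               sd = c(all_s, m_s, f_s))
  out <- rbind(
    row("n",                   100,   NA,   53,   NA,  47,  NA),
    row("weight_kg",            72,   14,   78,   14,  64,  11),
    row("height_m",            1.7,  0.1,  1.7,  0.1, 1.6, 0.1),
    row("bmi_kg_m2",            25,    4,   26,    4,  24,   4),
    row("age_years",            64,   13,   63,   12,  65,  14),
    row("total_volume_ml",    4995, 1313, 5757, 1127, 4136, 923),
    row("gas_volume_ml",      4066, 1190, 4729, 1033, 3319, 875),
    row("lung_weight_g",       929,  188, 1029,  168,  817, 140),
    row("overinflated_pct",     11,    7,   12,    6,    9,   7),
    row("well_inflated_pct",    65,    8,   64,    8,   66,   8),
    row("poorly_inflated_pct",  18,    3,   18,    3,   18,   3),
    row("noninflated_pct",       7,    4,    6,    4,    7,   4),
    row("mean_hu",            -805,   48, -816,   33, -792,  58),
    row("avg_sp_cmh2o",        2.6,  0.5,  2.6,  0.6,  2.6, 0.6))
  out
}

# Internal: fetch one (variable, group) mean or sd from the reference table.
ref_value <- function(variable, group = "all", what = c("mean", "sd")) {
  what <- match.arg(what)
  ref <- reference_population()
  v <- ref[ref$variable == variable & ref$group == group, what]
  if (length(v) != 1L)
    stop("unknown reference variable '", variable, "'", call. = FALSE)
  v
}
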