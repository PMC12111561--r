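#' Default group-by-timepoint effect table for the synthetic cohort
#'
#' Long-format table of means and SDs for every simulated variable at every
#' group x day, encoding the study design: five arms (adenine-fed sham +
#' vehicle; ischaemia-reperfusion injury (IRI) + vehicle; IRI + nicotinamide
#' riboside; IRI + SkQR1; IRI + both), measurements at days 0 (baseline),
#' 56 (subclinical CKD, day of surgery), 57 (1 day post), 63 (1 week post)
#' and 98 (endpoint). Vehicle-treated IRI animals sustain a large chronic
#' deficit in kidney functional reserve and renal blood volume with elevated
#' urinary injury biomarkers; treated arms largely recover. Units: GFR
#' mL/min, sCr umol/L, uCr mmol/L, urine flow mL/min, biomarkers ng/mL,
#' rBV percent.
#'
#' @return data.frame with columns `group`, `day`, `variable`, `mean`, `sd`.
#' @export
default_cohort_effects <- function() {
  groups <- c("sham+Veh", "IRI+Veh", "IRI+NR", "IRI+SkQR1", "IRI+NR+SkQR1")
  vars <- c("gfr_unstimulated", "gfr_stimulated", "scr", "ucr",
            "urine_flow", "ukim1", "uclu", "rbv_percent")
  sds <- c(gfr_unstimulated = 0.08, gfr_stimulated = 0.08, scr = 5,
           ucr = 1, urine_flow = 0.004, ukim1 = 1, uclu = 15,
           rbv_percent = 2)
  # means[day][state]: healthy baseline, sCKD, acute injury, partial
  # recovery, chronic deficit, treated recovery
  m <- function(gu, gs, scr, ukim1, uclu, rbv)
    c(gfr_unstimulated = gu, gfr_stimulated = gs, scr = scr, ucr = 6,
      urine_flow = 0.02, ukim1 = ukim1, uclu = uclu, rbv_percent = rbv)
  states <- list(
    healthy  = m(1.10, 1.60, 25, 0.5, 10, 30),
    sckd     = m(0.90, 1.25, 32, 1.5, 30, 26),
    acute    = m(0.35, 0.40, 95, 12.0, 150, 10),
    acute_tx = m(0.45, 0.60, 75, 8.0, 100, 14),
    partial  = m(0.55, 0.65, 60, 8.0, 100, 14),
    part_tx  = m(0.70, 0.95, 45, 4.0, 60, 20),
    chronic  = m(0.60, 0.68, 55, 7.0, 120, 13),
    recover  = m(0.85, 1.20, 38, 2.0, 40, 23),
    rec_dual = m(0.90, 1.30, 35, 1.6, 35, 25),
    sham_end = m(1.00, 1.45, 28, 1.0, 20, 28)
  )
  pick <- function(group, day) {
    treated <- group %in% c("IRI+NR", "IRI+SkQR1", "IRI+NR+SkQR1")
    switch(as.character(day),
      "0"  = states$healthy,
      "56" = states$sckd,
      "57" = if (group == "sham+Veh") states$sckd
             else if (treated) states$acute_tx else states$acute,
      "63" = if (group == "sham+Veh") states$sckd
             else if (treated) states$part_tx else states$partial,
      "98" = if (group == "sham+Veh") states$sham_end
             else if (group == "IRI+NR+SkQR1") states$rec_dual
             else if (treated) states$recover else states$chronic)
  }
  rows <- list()
  for (g in groups) for (d in c(0, 56, 57, 63, 98)) {
    mu <- pick(g, d)
    rows[[paste(g, d)]] <- data.frame(group = g, day = d, variable = vars,
                                      mean = unname(mu[vars]),
                                      sd = unname(sds[vars]),
                                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameters for the synthetic cohort generator
#'
#' @param groups study arms; defaults to the five-arm design.
#' @param n_per_group animals per arm (>= 2; study convention is 6).
#' @param timepoints measurement days.
#' @param effects long-format data.frame `group`, `day`, `variable`,
#'   `mean`, `sd` (defaults to [default_cohort_effects()]); must cover
#'   every group x day.
#' @param seed integer seed.
#' @return A validated list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(groups = c("sham+Veh", "IRI+Veh", "IRI+NR",
                                         "IRI+SkQR1", "IRI+NR+SkQR1"),
                              n_per_group = 6,
                              timepoints = c(0, 56, 57, 63, 98),
                              effects = default_cohort_effects(),
                              seed = 1L) {
  if (n_per_group < 2) stop_quant("n_per_group must be >= 2")
  need <- c("group", "day", "variable", "mean", "sd")
  if (!all(need %in% names(effects)))
    stop_quant("effects must have columns: %s", paste(need, collapse = ", "))
  if (any(effects$sd < 0)) stop_quant("effect SDs must be >= 0")
  for (g in groups) for (d in timepoints)
    if (!any(effects$group == g & effects$day == d))
      stop_quant("effects table has no rows for group '%s' day %s", g, d)
  structure(list(groups = groups, n_per_group = n_per_group,
                 timepoints = timepoints, effects = effects, seed = seed),
            class = "cohort_sim_params")
}

#' Generate a synthetic cohort table
#'
#' One row per animal x timepoint, each variable drawn from its group x day
#' normal distribution (truncated at zero for concentrations and flows).
#'
#' @param params a [cohort_sim_params()] object.
#' @return data.frame `animal_id`, `group`, `day`, plus one column per
#'   simulated variable; the `"effects"` attribute records the generating
#'   table.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_seed(p$seed, {
    vars <- unique(p$effects$variable)
    rows <- list()
    for (g in p$groups) for (a in seq_len(p$n_per_group)) {
      aid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", g), a)
      for (d in p$timepoints) {
        e <- p$effects[p$effects$group == g & p$effects$day == d, , drop = FALSE]
        draw <- stats::setNames(
          pmax(0, stats::rnorm(nrow(e), e$mean, e$sd)), e$variable)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(animal_id = aid, group = g, day = d,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(draw[vars])))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "effects") <- p$effects
    out
  })
}
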