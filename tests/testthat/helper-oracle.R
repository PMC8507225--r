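# Independent scalar brute-force oracle for the cohort engine: a plain loop
# over named scalar state probabilities, written directly from the model
# definition (weekly exacerbation probability split by type, compounded
# weekly mortality, transient one-cycle exacerbation states). Shares no code
# with run_cohort()/accrue_outcomes().

oracle_trace <- function(arm, params, config, lt, n_cycles) {
  qxF <- lt$qx[lt$sex == "F"][order(lt$age[lt$sex == "F"])]
  qxM <- lt$qx[lt$sex == "M"][order(lt$age[lt$sex == "M"])]
  cpy <- config$cycles_per_year
  shares <- arm$exac_type_shares
  s <- c(non = 1, scs = 0, ed = 0, ip = 0, death = 0)
  rows <- matrix(NA_real_, n_cycles, 5)
  for (t in seq_len(n_cycles)) {
    age <- floor(config$start_age + (t - 1) / cpy)
    wF <- 1 - (1 - qxF[age + 1])^(1 / cpy)
    wM <- 1 - (1 - qxM[age + 1])^(1 / cpy)
    w_bg <- config$sex_mix * wF + (1 - config$sex_mix) * wM
    p_ex <- 1 - exp(-arm$annual_severe_exac_rate / cpy)
    die_exac <- vapply(c("SCS", "ED_SCS", "INPATIENT"), function(nm) {
      min(w_bg + 1 - (1 - params$exac_types[[nm]]$annual_asthma_death_risk)^(1 / cpy), 1)
    }, numeric(1))
    new <- c(
      non = s[["non"]] * (1 - p_ex - w_bg) +
        s[["scs"]] * (1 - die_exac[["SCS"]]) +
        s[["ed"]] * (1 - die_exac[["ED_SCS"]]) +
        s[["ip"]] * (1 - die_exac[["INPATIENT"]]),
      scs = s[["non"]] * p_ex * shares[["SCS"]],
      ed = s[["non"]] * p_ex * shares[["ED_SCS"]],
      ip = s[["non"]] * p_ex * shares[["INPATIENT"]],
      death = s[["death"]] + s[["non"]] * w_bg +
        s[["scs"]] * die_exac[["SCS"]] + s[["ed"]] * die_exac[["ED_SCS"]] +
        s[["ip"]] * die_exac[["INPATIENT"]]
    )
    s <- new
    rows[t, ] <- s
  }
  colnames(rows) <- c("NONEXAC", "EXAC_SCS", "EXAC_ED_SCS", "EXAC_INPATIENT",
                      "DEATH")
  rows
}

# Small flat life table for fast, transparent engine tests.
flat_life_table <- function(qx = 0.01, max_age = 110) {
  ages <- 0:max_age
  q <- rep(qx, length(ages)); q[length(q)] <- 1
  life_table(c(ages, ages), c(rep("F", length(ages)), rep("M", length(ages))),
             c(q, q))
}

zero_mortality_params <- function(params) {
  for (nm in names(params$exac_types))
    params$exac_types[[nm]]$annual_asthma_death_risk <- 0
  params
}
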