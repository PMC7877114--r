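# Independent oracles used by unit and acceptance tests. These re-derive
# results by explicit scanning/enumeration and deliberately share no code
# with the implementation.

# Greedy 1:1 matcher oracle: explicit per-record scan under the documented
# total order (ascending index date then id; final-date proximity, then
# index-date proximity, then id).
brute_force_match <- function(rec, mode, delta) {
  adj <- rec
  comp <- adj$group == "comparator"
  for (col in c("baseline_sbp", "final_sbp")) {
    adj[[col]][comp] <- adj[[col]][comp] - delta
  }
  key <- function(i) {
    age <- as.integer(format(adj$baseline_date[i], "%Y")) -
      adj$year_of_birth[i]
    g <- switch(mode,
                exact = adj$baseline_sbp[i],
                nearest_0_or_5 = round(adj$baseline_sbp[i] / 5) * 5,
                nearest_0 = floor(adj$baseline_sbp[i] / 10 + 0.5) * 10)
    paste(adj$simd_decile[i], adj$sex[i], (age %/% 10), g)
  }
  tms <- which(adj$group == "telemonitoring")
  tms <- tms[order(adj$baseline_date[tms], adj$patient_id[tms])]
  cps <- which(comp)
  used <- c()
  out <- list()
  for (i in tms) {
    elig <- cps[!(cps %in% used) & sapply(cps, key) == key(i)]
    if (length(elig) == 0) next
    d1 <- abs(as.numeric(adj$final_date[elig] - adj$final_date[i]))
    d2 <- abs(as.numeric(adj$baseline_date[elig] - adj$baseline_date[i]))
    best <- elig[order(d1, d2, adj$patient_id[elig])][1]
    used <- c(used, best)
    out[[length(out) + 1]] <- c(adj$patient_id[i], adj$patient_id[best])
  }
  if (length(out) == 0) return(character(0))
  sapply(out, paste, collapse = "->")
}

# Random small matching instance with coarse covariates (so exact criteria
# are satisfiable at tiny n).
random_match_instance <- function(seed, n = NULL) {
  set.seed(seed)
  n <- n %||% sample(3:8, 1)
  rec <- make_records(n_per_group = n, seed = seed + 5000)
  rec$simd_decile <- sample(4:5, nrow(rec), TRUE)
  rec$year_of_birth <- sample(c(1945L, 1955L), nrow(rec), TRUE)
  rec$age_2015 <- 2015 - rec$year_of_birth
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
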