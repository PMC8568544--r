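# hand-built cohort rows for exercising the data model without the generator
toy_cohort <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    city = "Beijing", age_years = 45, sex = 0, education = 1,
    income_band = 1, insurance = "URBMI",
    smoking = 0, drinking = 0, exercise = 0, diet_control = 0,
    duration_band = 1, heart_disease = 0, hypertension = 0,
    dyslipidemia = 0, stroke = 0,
    bmi = 22, fbs = 6, hba1c = 7, sbp = 120, dbp = 80, tc = 4, tg = 1,
    eq5d = 0.8, hypo_baseline = 0,
    drugs_baseline = "metformin",
    drugs_fu1 = "metformin", drugs_fu2 = "metformin",
    drugs_fu3 = "metformin", drugs_fu4 = "metformin",
    hypo_fu1 = 0, hypo_fu2 = 0, hypo_fu3 = 0, hypo_fu4 = 0,
    endpoint_hba1c = 7, endpoint_eq5d = 0.8,
    cost_inpatient = 1, cost_outpatient = 1, cost_otc = 1
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# brute-force minimal edge clique cover of the "not significantly different"
# graph: the smallest number of letters any valid display could use
min_letter_count <- function(p, alpha = 0.05) {
  k <- nrow(p)
  compat <- p >= alpha
  diag(compat) <- TRUE
  # enumerate all cliques of the compatibility graph
  subsets <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(k, m, simplify = FALSE)
  }), recursive = FALSE)
  cliques <- subsets[vapply(subsets, function(s) all(compat[s, s]), logical(1))]
  edges <- which(upper.tri(compat) & compat, arr.ind = TRUE)
  singletons <- seq_len(k)
  covers_ok <- function(chosen) {
    # every compatible pair shares a clique and every group appears somewhere
    if (!all(singletons %in% unlist(chosen))) return(FALSE)
    if (nrow(edges) == 0) return(TRUE)
    all(apply(edges, 1, function(e) {
      any(vapply(chosen, function(cl) all(e %in% cl), logical(1)))
    }))
  }
  for (m in seq_along(cliques)) {
    combos <- utils::combn(length(cliques), m, simplify = FALSE)
    for (cm in combos) {
      if (covers_ok(cliques[cm])) return(m)
    }
  }
  stop("no cover found")
}

# reconstruct the "share a letter" relation from a letter display
letters_relation <- function(letter_strings) {
  k <- length(letter_strings)
  rel <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      li <- strsplit(letter_strings[i], "")[[1]]
      lj <- strsplit(letter_strings[j], "")[[1]]
      rel[i, j] <- length(intersect(li, lj)) > 0
    }
  }
  rel
}
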