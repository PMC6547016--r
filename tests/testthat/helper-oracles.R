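# Independent oracles and tiny fixture builders used across test files.

# All-pairs AUROC: P(score_pos > score_neg) + 0.5 * P(tie).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Gini impurity mass of a node in count units.
oracle_gini_mass <- function(y) {
  n <- length(y)
  if (n == 0) return(0)
  p <- mean(y)
  2 * n * p * (1 - p)
}

# Exhaustive search over all k-subsets of candidate cut positions (midpoints
# between consecutive distinct values), maximising the total impurity
# decrease of the resulting (k+1)-way partition. Ties break toward the
# lexicographically smallest cut set.
oracle_best_cuts <- function(x, y, k = 3, min_n = 1) {
  xs <- sort(unique(x))
  cands <- (xs[-length(xs)] + xs[-1]) / 2
  if (length(cands) < k) stop("not enough distinct values")
  combos <- utils::combn(cands, k)
  best <- NULL
  best_mass <- Inf
  for (j in seq_len(ncol(combos))) {
    cuts <- combos[, j]
    g <- findInterval(x, cuts, left.open = TRUE)
    sizes <- tabulate(g + 1L, nbins = k + 1)
    if (any(sizes < min_n)) next
    mass <- sum(vapply(0:k, function(b) oracle_gini_mass(y[g == b]), numeric(1)))
    if (mass < best_mass - 1e-12) {
      best_mass <- mass
      best <- cuts
    }
  }
  best
}

# Direct oxygen-fraction mixing: pure O2 flow plus entrained air at 21%.
oracle_mix_fio2 <- function(flow, rr, vt = 0.45) {
  mv <- rr * vt
  air <- mv - flow
  (flow * 1.0 + air * 0.21) / mv
}

# A complete, unremarkable observation row; override fields as needed.
make_obs <- function(..., n = 1) {
  base <- tibble::tibble(
    admission_id = "A1",
    timestamp = as.POSIXct("2024-03-01 08:00:00", tz = "UTC"),
    hr = 70, rr = 16, sbp = 120, spo2 = 98, temp = 36.8,
    avpu = "A", gcs = NA_integer_,
    device = "room_air", o2_flow_lpm = NA_real_, prescribed_fio2 = NA_real_
  )
  out <- base[rep(1, n), ]
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

make_adm <- function(..., n = 1) {
  base <- tibble::tibble(
    admission_id = "A1", patient_id = "P1", age_years = 60L,
    admit_time = as.POSIXct("2024-03-01 00:00:00", tz = "UTC"),
    discharge_time = as.POSIXct("2024-03-05 00:00:00", tz = "UTC"),
    outcome = "none", event_time = as.POSIXct(NA, tz = "UTC"),
    planned_icu_before_ward = FALSE
  )
  out <- base[rep(1, n), ]
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

hrs <- function(h) h * 3600
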