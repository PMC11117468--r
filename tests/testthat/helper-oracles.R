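# Independent oracles kept deliberately naive: direct formula evaluation,
# exhaustive enumeration, brute-force definitions. They never call the
# package code paths they check.

# 2009 CKD-EPI creatinine equation, written out term by term
oracle_ckdepi_2009 <- function(cr, age, sex, race = 1) {
  kappa <- if (sex == "female") 0.7 else 0.9
  alpha <- if (sex == "female") -0.329 else -0.411
  f <- if (sex == "female") 1.018 else 1
  141 * min(cr / kappa, 1)^alpha * max(cr / kappa, 1)^(-1.209) *
    0.993^age * f * race
}

# AUC by exhaustive diseased x non-diseased pair enumeration, ties = 1/2
oracle_auc_pairs <- function(scores, truths) {
  pos <- scores[truths]
  neg <- scores[!truths]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the step-up definition with cumulative-minimum
# enforcement
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(adj_sorted, 1)[order(o)]
}

# Kruskal-Wallis H from first principles: mid-ranks, between-group rank
# sum, tie-corrected
oracle_kw_h <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# small well-formed patient table (eGFR supplied, creatinine consistent)
make_patient_df <- function(n = 3) {
  age <- c(72, 60, 55, 80, 45)[seq_len(n)]
  sex <- rep(c("male", "female"), length.out = n)
  egfr <- c(9.9, 44.4, 34.9, 23.7, 60)[seq_len(n)]
  data.frame(
    id = paste0("P", seq_len(n)),
    age = age,
    sex = sex,
    lc_type = rep(c("kappa", "lambda"), length.out = n),
    serum_creatinine = creatinine_from_egfr(egfr, age, sex),
    egfr = egfr,
    involved_flc_serum = c(598, 21.1, 29.3, 95.5, 10)[seq_len(n)],
    involved_lc_urine = c(171.5, 15.9, 5.7, 48.6, 2)[seq_len(n)],
    proteinuria = c(3929, 2565, 1200, 5000, 800)[seq_len(n)],
    histology = c("Cast nephropathy", "AL amyloidosis", "IgA glomerulonephritis",
                  "MIDD", "Nephroangiosclerosis")[seq_len(n)],
    stringsAsFactors = FALSE
  )
}
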