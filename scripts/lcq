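#!/usr/bin/env Rscript
# Thin command-line wrapper over the lcquotient package.
#
#   lcq simulate --seed N --out cohort.csv [--n-scale K]
#   lcq validate <cohort.csv> [--lenient]
#   lcq summarize <cohort.csv>
#   lcq classify <cohort.csv> [--lambda-cut 2 --kappa-high 5 --kappa-low 1
#                              --proteinuria-cut 8000] [--out preds.csv]
#   lcq evaluate <cohort.csv> [--json report.json]
#   lcq compare <cohort.csv>
#   lcq run <cohort.csv> [--json report.json]
#   lcq replicate-table
#   lcq egfr --creatinine X --age N --sex female|male [--version 2009|2021]

suppressPackageStartupMessages(library(lcquotient))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0) stop("usage: lcq <subcommand> [options]; see script header")
cmd <- argv[1]
rest <- argv[-1]

flag <- function(name, default = NULL) {
  i <- which(rest == paste0("--", name))
  if (length(i) == 0) return(default)
  rest[i + 1]
}
num_flag <- function(name, default) as.numeric(flag(name, default))
positional <- rest[!grepl("^--", rest) &
                     !seq_along(rest) %in% (which(grepl("^--", rest)) + 1)]

thresholds_from_flags <- function() {
  rule_thresholds(
    lambda_cut = num_flag("lambda-cut", 2),
    kappa_high_cut = num_flag("kappa-high", 5),
    kappa_low_cut = num_flag("kappa-low", 1),
    proteinuria_cut = num_flag("proteinuria-cut", 8000)
  )
}

switch(cmd,
  simulate = {
    spec <- cohort_spec(n_scale = as.integer(num_flag("n-scale", 1)))
    ch <- generate_cohort(spec, seed = as.integer(num_flag("seed", 1)))
    out <- flag("out", "cohort.csv")
    write_cohort(ch, out)
    cat("wrote", out, "(", nrow(ch), "patients )\n")
  },
  validate = {
    ch <- read_cohort(positional[1], strict = !("--lenient" %in% rest))
    cat("valid cohort:", nrow(ch), "patients;",
        nrow(attr(ch, "dropped")), "row(s) dropped\n")
  },
  summarize = {
    cnt <- cohort_summary_counts(read_cohort(positional[1]))
    cat("n =", cnt$n, "; cast nephropathy =", cnt$n_cn, "\n")
    print(cnt$histology); print(cnt$lc_type); print(cnt$sex)
  },
  classify = {
    preds <- apply_rule(read_cohort(positional[1]), thresholds_from_flags())
    out <- flag("out")
    if (is.null(out)) {
      print(as.data.frame(preds))
    } else {
      readr::write_csv(as.data.frame(preds), out)
      cat("wrote", out, "\n")
    }
    ex <- attr(preds, "excluded")
    if (nrow(ex) > 0) {
      cat("excluded:\n"); print(as.data.frame(ex))
    }
  },
  evaluate = ,
  run = {
    rep <- run_analysis(read_cohort(positional[1]), thresholds_from_flags())
    print(rep)
    json <- flag("json")
    if (!is.null(json)) { report_to_json(rep, json); cat("wrote", json, "\n") }
  },
  compare = {
    ch <- read_cohort(positional[1])
    print(as.data.frame(summarize_groups(ch)))
    for (v in c("quotient", "egfr", "involved_flc_serum", "involved_lc_urine")) {
      cg <- compare_groups(ch, v)
      cat("\n==", v, "==\n"); print(cg$omnibus)
      if (!is.null(cg$pairwise)) print(as.data.frame(cg$pairwise))
    }
  },
  `replicate-table` = print(replicate_reference_metrics()),
  egfr = {
    cat(egfr_ckdepi(num_flag("creatinine", NA), num_flag("age", NA),
                    flag("sex"),
                    ckdepi_params(flag("version", "2009"))), "\n")
  },
  stop("unknown subcommand: ", cmd)
)
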