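#!/usr/bin/env Rscript
# Thin command-line wrapper over the prepostCE package.
#
#   Rscript scripts/cea_pipeline.R <subcommand> [options]
#
# Subcommands:
#   simulate --n 44 --seed 1 --out cohort.csv        write a synthetic cohort
#   cost     --cohort cohort.csv --period baseline   per-category cost summary
#   cea      --cohort cohort.csv --measure act_points [--wtp 24000]
#   cua      --cohort cohort.csv [--wtp 24000]
#   psa      --cohort cohort.csv --n 10000 --seed 1 --out-samples psa.csv
#            [--out-ceac ceac.csv]                   PSA samples + CEAC data
#   report   --seed 1 --out-dir results/ [--cohort cohort.csv]
#
# Exit codes: 0 ok, 1 validation error, 2 runtime error.

suppressMessages(library(prepostCE))

parse_opts <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    opt[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  opt
}

main <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  if (length(args) == 0) stop("no subcommand given")
  cmd <- args[1]
  opt <- parse_opts(args[-1])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  get_cohort <- function() {
    if (is.null(opt$cohort)) {
      generate_cohort(default_cohort_params(seed = num(opt$seed, 1)))
    } else read_cohort(opt$cohort)
  }
  switch(cmd,
    simulate = {
      co <- generate_cohort(default_cohort_params(n = num(opt$n, 44)),
                            seed = num(opt$seed, 1))
      write_cohort(co, opt$out %||% stop("simulate needs --out"))
      cat("wrote", length(unique(co$patient_id)), "patients to", opt$out, "\n")
    },
    cost = {
      print(cohort_cost_summary(get_cohort(), opt$period %||% "baseline"),
            n = Inf)
    },
    cea = {
      co <- get_cohort()
      m <- opt$measure %||% "act_points"
      d_e <- mean(prepostCE:::patient_eff_diffs(co, m))
      dc <- mean(patient_total_costs(co, "treatment")) -
        mean(patient_total_costs(co, "baseline"))
      print(ce_result(0, dc, 0, d_e, wtp = num(opt$wtp, 24000), measure = m))
    },
    cua = {
      co <- get_cohort()
      iu <- incremental_utility(co)
      dc <- mean(patient_total_costs(co, "treatment")) -
        mean(patient_total_costs(co, "baseline"))
      print(ce_result(0, dc, iu$baseline_mean, iu$treatment_mean,
                      wtp = num(opt$wtp, 24000), measure = "utility"))
    },
    psa = {
      co <- get_cohort()
      pin <- psa_inputs_from_cohort(co, opt$measure %||% "utility")
      s <- psa_simulate(pin$cost_pre, pin$cost_post, pin$eff_pre,
                        pin$eff_post, n = num(opt$n, 10000),
                        seed = num(opt$seed, 1), eff_bounds = pin$eff_bounds)
      s$nmb <- nmb(s$delta_eff, s$delta_cost, num(opt$wtp, 24000))
      utils::write.csv(s, opt$out_samples %||% stop("psa needs --out-samples"),
                       row.names = FALSE)
      if (!is.null(opt$out_ceac)) {
        utils::write.csv(ceac(s, seq(1000, 50000, by = 1000)), opt$out_ceac,
                         row.names = FALSE)
      }
      cat("probability cost-effective at", num(opt$wtp, 24000), "EUR:",
          prob_cost_effective(s, num(opt$wtp, 24000)), "\n")
    },
    report = {
      cfg <- run_config(cohort = opt$cohort, seed = num(opt$seed, 1),
                        output_dir = opt$out_dir %||% "results")
      res <- run_full_analysis(cfg)
      print(res)
      cat("report written to", cfg$output_dir, "\n")
    },
    stop("unknown subcommand: ", cmd)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

status <- tryCatch({ main(); 0 },
  prepostCE_error = function(e) { message("validation error: ",
                                          conditionMessage(e)); 1 },
  error = function(e) { message("error: ", conditionMessage(e)); 2 })
quit(status = status)
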