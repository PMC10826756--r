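#!/usr/bin/env Rscript
# Step 3: extrapolate each era's fitted power law below its threshold (the
# "expected line") and difference it against the observed histogram to get
# the annual deficit of small (<10 confirmed cases) and large (>=100)
# outbreaks and their associated illnesses. The generator's ground truth
# says how many small outbreaks were actually censored, so the estimates can
# be judged against the construction.

suppressPackageStartupMessages(library(outbreaklaw))

recs <- read_outbreaks("results/data/synthetic_outbreaks.csv")
truth <- utils::read.delim("results/data/era_truth.tsv")
hists <- split_eras(recs)

rows <- list()
for (nm in names(hists)) {
  h <- hists[[nm]]
  fit <- select_xmin(h, "power_law")
  line <- expected_line(fit, h)
  od <- outbreak_deficit(line, h)
  il <- suppressMessages(illness_deficit(line, h))
  rows[[nm]] <- data.frame(
    era = nm, n = h$total, xmin = fit$model$xmin, alpha = fit$model$alpha,
    ks = fit$ks_distance,
    small_deficit_annual = od$small_outbreak_deficit_annual,
    large_deficit_annual = od$large_outbreak_deficit_annual,
    small_illness_deficit_annual = il$small_illness_deficit_annual,
    large_illness_deficit_annual = il$large_illness_deficit_annual)
  utils::write.table(observed_expected_table(line),
                     sprintf("results/observed_expected_%s.tsv", nm),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
out <- do.call(rbind, rows)
print(out, row.names = FALSE)

true_annual <- truth$censored_small_annual[match(c(1998, 2018), truth$first_year)]
message(sprintf("construction truth, censored small outbreaks/yr: era1 %.1f, era2 %.1f",
                true_annual[1], true_annual[2]))
message(sprintf("estimated small deficit/yr:                      era1 %.1f, era2 %.1f",
                out$small_deficit_annual[out$era == "era1"],
                out$small_deficit_annual[out$era == "era2"]))

utils::write.table(out, "results/deficits.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("wrote results/deficits.tsv and per-era observed/expected tables")
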