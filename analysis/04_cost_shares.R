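#!/usr/bin/env Rscript
# Component shares of the total time and direct cost of a visit, under the
# one-way and round-trip journey conventions: first from the published
# component means of the Tanzanian survey, then from the synthetic survey.

suppressPackageStartupMessages(library(equicost))

published_time <- c(travel_time = 30.1, waiting_time = 46.7,
                    consultation_time = 12.9)
published_direct <- c(transport_cost = 0.41, medical_cost = 0.23)

rows <- list()
for (conv in c("one_way", "round_trip")) {
  for (fam in c("time", "direct")) {
    comp <- if (fam == "time") published_time else published_direct
    br <- share_decomposition(comp, conv)
    rows[[paste(fam, conv)]] <- data.frame(
      source = "published_means", family = fam, convention = conv,
      component = names(br$shares), total = br$total,
      share_pct = 100 * unname(br$shares))
  }
}
pub <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(pub, "results/shares_published.csv", row.names = FALSE)

ow <- share_decomposition(published_time, "one_way")
rt <- share_decomposition(published_time, "round_trip")
message(sprintf(
  "One-way visit: %.0f min total; waiting %.1f%%, travel %.1f%%, consultation %.1f%%.",
  ow$total, 100 * ow$shares[["waiting_time"]],
  100 * ow$shares[["travel_time"]], 100 * ow$shares[["consultation_time"]]))
message(sprintf(
  "Round trip: %.0f min; travel overtakes waiting (%.1f%% vs %.1f%%).",
  rt$total, 100 * rt$shares[["travel_time"]], 100 * rt$shares[["waiting_time"]]))
dow <- share_decomposition(published_direct, "one_way")
message(sprintf(
  "Direct cost: transport takes %.1f%% one-way, %.1f%% round trip.",
  100 * dow$shares[["transport_cost"]],
  100 * share_decomposition(published_direct, "round_trip")$shares[["transport_cost"]]))

# same decomposition on the synthetic survey's own means (already written by
# 03 into results/tables/shares.csv)
syn <- read.csv("results/tables/shares.csv")
w <- syn[syn$family == "time" & syn$convention == "one_way" &
         syn$component == "waiting_time", "share_pct"]
message(sprintf("Synthetic survey one-way waiting share: %.1f%% (cf. 52.1%%).", w))
message("Wrote results/shares_published.csv.")
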