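#!/usr/bin/env Rscript
# Time-series figures of the warming experiment: the oxygen-budget
# components (abiotic tracer, -TOU, cumulative air-sea flux, their sum),
# the oxygen change against flux + nitrate-loss equivalent, and the
# biology panel (NCP, denitrification, fixation, suboxic volume).

library(oxybox)
library(ggplot2)

g <- read.csv("results/run_warming.csv", check.names = FALSE)
yr <- g[["time.yr"]]
dir.create("results/figures", showWarnings = FALSE)

anom <- function(x) x - x[1]
budget <- rbind(
  data.frame(yr, value = anom(g[["abio_inv.Pmol"]]), series = "abiotic O2"),
  data.frame(yr, value = -anom(g[["tou_inv.Pmol"]]), series = "-TOU"),
  data.frame(yr, value = g[["cum_airsea.Pmol"]], series = "cumulative air-sea flux"),
  data.frame(yr, value = anom(g[["abio_inv.Pmol"]]) - anom(g[["tou_inv.Pmol"]]),
             series = "abiotic + (-TOU)"))
ggsave("results/figures/budget_components.pdf", width = 7, height = 4.5,
       plot = ggplot(budget, aes(yr, value, colour = series)) +
         geom_line() + labs(x = "year", y = "anomaly (Pmol O2)") +
         theme_minimal())

s <- stoich_params()
gain <- rbind(
  data.frame(yr, value = anom(g[["o2_inv.Pmol"]]), series = "O2 inventory"),
  data.frame(yr, value = g[["cum_airsea.Pmol"]], series = "cumulative air-sea flux"),
  data.frame(yr, value = o2_equivalent_of_nitrate_loss(
    -(anom(g[["no3_inv.Pmol"]])), s), series = "nitrate-loss O2 equivalent"))
ggsave("results/figures/oxygen_gain.pdf", width = 7, height = 4.5,
       plot = ggplot(gain, aes(yr, value, colour = series)) +
         geom_line() + labs(x = "year", y = "anomaly (Pmol O2)") +
         theme_minimal())

bio <- rbind(
  data.frame(yr, value = g[["ncp_rate.TmolP.yr"]] * 10, series = "NCP (x10, Tmol P/yr)"),
  data.frame(yr, value = g[["denit_rate.TmolN.yr"]], series = "denitrification (Tmol N/yr)"),
  data.frame(yr, value = g[["fixation_rate.TmolN.yr"]], series = "N2 fixation (Tmol N/yr)"),
  data.frame(yr, value = g[["suboxic_vol.m3"]] / 1e16, series = "suboxic volume (1e16 m3)"))
ggsave("results/figures/biology.pdf", width = 7, height = 5.5,
       plot = ggplot(bio, aes(yr, value)) + geom_line() +
         facet_wrap(~series, scales = "free_y", ncol = 1) +
         labs(x = "year", y = NULL) + theme_minimal())

message("wrote results/figures/*.pdf")
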