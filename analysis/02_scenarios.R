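#!/usr/bin/env Rscript
# Run the three experiments from the spun-up state: the prescribed
# multi-millennial warming scenario (+3.1 degC volume-mean ocean warming by
# year 3380, overturning dip and recovery), the pre-industrial control, and
# the counterfactual in which nitrogen fixation compensates
# denitrification instantaneously. Writes annual diagnostics CSVs.

library(oxybox)
cfg <- read_config_yaml("results/config.yaml")
state <- read_state_csv("results/spun_state.csv")

frc <- make_warming_scenario(geometry = cfg$geometry)
write_forcing_csv(frc, "results/forcing_warming.csv")
ctl <- make_control_scenario(geometry = cfg$geometry)

for (x in list(list("warming", cfg, frc),
               list("control", cfg, ctl),
               list("counterfactual", instant_fixation_config(cfg), frc))) {
  message("running ", x[[1]], " ...")
  run <- run_simulation(x[[2]], state, x[[3]])
  print(run)
  write_run_csv(run, file.path("results", paste0("run_", x[[1]], ".csv")))
}
message("wrote results/run_{warming,control,counterfactual}.csv")
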