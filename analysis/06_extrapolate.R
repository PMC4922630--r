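#!/usr/bin/env Rscript
# Convert net transition probabilities into net numbers of people
# transitioning per year, using synthetic single-year-of-age population
# counts.

suppressPackageStartupMessages(library(bmitrans))
out <- "results"

nets <- read.csv(file.path(out, "net_transitions.csv"))
ext <- NULL
for (s in c("male", "female")) {
  cv <- readRDS(file.path("scratch", paste0("curve_", s, ".rds")))
  pop <- synthetic_population_counts(sex = s, group = "GroupA", base = 3e5)
  tab <- nets[nets$sex == s, setdiff(names(nets), "sex")]
  e <- extrapolate_counts(tab, cv, pop)
  ext <- rbind(ext, cbind(sex = s, e))
  up2 <- e[e$boundary == "overweight_obese" & e$direction == "up", ]
  cat(sprintf("%s: net persons to obesity peaks at age %d (%s persons/yr); age-2 value %s\n",
              s, up2$age[which.max(up2$net_count)],
              format(max(up2$net_persons), big.mark = ","),
              format(up2$net_persons[up2$age == 2], big.mark = ",")))
}
write.csv(ext, file.path(out, "net_transition_counts.csv"), row.names = FALSE)
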