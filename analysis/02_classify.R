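#!/usr/bin/env Rscript
# Apply the eligibility filters and assign the three ordered weight
# categories (BMI cut-points for adults, growth-reference percentiles for
# children).

suppressPackageStartupMessages(library(bmitrans))
out <- "results/data"

records <- read_records(file.path(out, "survey_records.csv"))
growth <- read_growth_reference(file.path(out, "growth_reference_synthetic.csv"))

excl <- apply_exclusions(records)
classified <- assign_categories(excl$eligible, growth)

write.csv(classified, file.path(out, "classified_records.csv"),
          row.names = FALSE)
jsonlite::write_json(excl$log, file.path(out, "exclusion_log.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("%d of %d records eligible; %d underweight adults folded into normal\n",
            excl$log$n_eligible, excl$log$n_input, excl$log$underweight_folded))
print(round(100 * prop.table(table(classified$category)), 1))
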