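#!/usr/bin/env Rscript
# Step 1: the EV catalog.
# Loads the built-in 2016 NEPHS catalog (38 items, 12 service types, two
# workload regions), confirms every EV is person-minutes / 15, and writes
# the catalog table used by the following steps.

suppressPackageStartupMessages(library(evworkload))
dir.create("results", showWarnings = FALSE)

catalog <- builtin_catalog()
print(catalog)

err <- max(abs(derive_ev(catalog$items$minutes) - catalog$items$ev))
cat(sprintf("EV identity (minutes / 15 vs catalog EV), max abs error: %g over %d cells\n",
            err, nrow(catalog$items)))

# the heaviest and lightest items per region, as a sanity read
items <- catalog$items
for (r in catalog$regions) {
  sub <- items[items$region == r, ]
  cat(sprintf("%s: heaviest item %s (EV %.1f), lightest %s (EV %.1f)\n",
              r, sub$item_id[which.max(sub$ev)], max(sub$ev),
              sub$item_id[which.min(sub$ev)], min(sub$ev)))
}

write_catalog(catalog, "results/ev_catalog.csv")
cat("wrote results/ev_catalog.csv\n")
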