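# Regenerates inst/extdata/catalog.json from the in-code registry.
# Run from the package root:  Rscript tools/make_catalog.R
pkgload::load_all(".", quiet = TRUE)

data <- acuhead:::build_catalog_data()
data$checksum <- acuhead:::acu_checksum(acuhead:::catalog_canonical(data))
jsonlite::write_json(data, "inst/extdata/catalog.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote inst/extdata/catalog.json with checksum", data$checksum, "\n")
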