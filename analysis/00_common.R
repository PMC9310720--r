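# Shared plumbing for the analysis scripts: configuration and cohort reload.
suppressPackageStartupMessages({
  library(mddburden)
  library(data.table)
})

cfg_file <- file.path("analysis", "config.yaml")
CFG <- yaml::read_yaml(cfg_file)
dir.create(CFG$results_dir, showWarnings = FALSE, recursive = TRUE)

read_members <- function() {
  m <- fread(file.path(CFG$results_dir, "cohort_members.csv"))
  for (col in c("index_date", "follow_up_end")) m[, (col) := as.Date(get(col))]
  m
}

registry <- function() load_tables(CFG$registry_dir)

save_csv <- function(dt, name) {
  path <- file.path(CFG$results_dir, paste0(name, ".csv"))
  fwrite(dt, path, dateTimeAs = "ISO", logical01 = FALSE, na = "", quote = FALSE)
  message("wrote ", path, " (", nrow(dt), " rows)")
}
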