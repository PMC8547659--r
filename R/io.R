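# CSV round trip for the declared input schemas (UTF-8, header row, '.'
# decimal separator).  Column names are part of the contract.

input_files <- function() {
  c(strata = "strata.csv", products = "products.csv", sales = "sales.csv",
    composition = "composition.csv", mapping = "mapping.csv",
    recalls = "recalls.csv", persons = "persons.csv",
    burden_events = "burden_events.csv", burden_causes = "burden_causes.csv",
    rr = "rr.csv", urinary = "urinary.csv", sbp_model = "sbp_model.csv")
}

#' Write a pipeline input bundle to CSV files
#'
#' One file per table (strata, products, sales, composition, mapping,
#' recalls, persons, burden events, burden causes, relative risks,
#' urinary means, SBP-model coefficients) plus one `targets_<name>.csv`
#' per target set.
#'
#' @param inputs a `cra_inputs` bundle (see [generate_inputs()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_input_tables <- function(inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- input_files()
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE)
  wr(inputs$strata, files["strata"])
  wr(inputs$products, files["products"])
  wr(inputs$sales, files["sales"])
  wr(inputs$composition, files["composition"])
  wr(inputs$mapping, files["mapping"])
  wr(inputs$recalls, files["recalls"])
  wr(inputs$persons, files["persons"])
  wr(inputs$burden$events, files["burden_events"])
  wr(inputs$burden$causes, files["burden_causes"])
  wr(inputs$rr, files["rr"])
  wr(data.frame(sex = names(inputs$urinary),
                urinary_mg_d = as.numeric(inputs$urinary),
                stringsAsFactors = FALSE), files["urinary"])
  wr(as.data.frame(inputs$sbp_model), files["sbp_model"])
  for (nm in names(inputs$targets)) {
    wr(inputs$targets[[nm]], sprintf("targets_%s.csv", nm))
  }
  invisible(dir)
}

#' Read a pipeline input bundle from CSV files
#'
#' Inverse of [write_input_tables()].  The burden table is validated on
#' read (inverted uncertainty bounds are rejected).
#'
#' @param dir directory written by [write_input_tables()].
#' @return a `cra_inputs` list (without the generator config).
#' @export
read_input_tables <- function(dir) {
  files <- input_files()
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  urinary_df <- rd(files["urinary"])
  urinary <- stats::setNames(urinary_df$urinary_mg_d, urinary_df$sex)
  sbp_df <- rd(files["sbp_model"])
  target_files <- list.files(dir, pattern = "^targets_.*\\.csv$")
  targets <- lapply(target_files, rd)
  names(targets) <- sub("^targets_(.*)\\.csv$", "\\1", target_files)
  burden <- list(events = rd(files["burden_events"]),
                 causes = rd(files["burden_causes"]))
  validate_burden(burden)
  out <- list(strata = rd(files["strata"]),
              products = rd(files["products"]),
              sales = rd(files["sales"]),
              composition = rd(files["composition"]),
              mapping = rd(files["mapping"]),
              recalls = rd(files["recalls"]),
              persons = rd(files["persons"]),
              burden = burden,
              rr = rd(files["rr"]),
              sbp_model = as.list(sbp_df),
              urinary = urinary,
              targets = targets)
  class(out) <- "cra_inputs"
  out
}
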