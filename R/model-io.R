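#' Save a layered model as a directory of text files
#'
#' Each ensemble member is serialized with [write_network()]; a JSON
#' manifest records the topology (setup, threshold, fold plan, member
#' files). Cross-validated training scores are not persisted -- a loaded
#' model predicts but does not re-report its training performance.
#'
#' @param model A `bturn_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(setup = model$setup, threshold = model$threshold,
                   types = model$types, seed = model$seed,
                   plan = model$plan, ensembles = list())
  dump_layer <- function(layer, name) {
    for (nm in names(layer)) {
      files <- character(0)
      for (i in seq_along(layer[[nm]]$members)) {
        fn <- sprintf("%s_%s_%03d.json", name, gsub("'", "p", nm), i)
        write_network(layer[[nm]]$members[[i]], file.path(dir, fn))
        files <- c(files, fn)
      }
      manifest$ensembles[[paste(name, nm, sep = ".")]] <<- files
    }
  }
  dump_layer(model$first, "first")
  dump_layer(model$second, "second")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a layered model saved by [write_model()]
#'
#' @param dir Model directory.
#' @return A `bturn_model` (prediction-ready; no training scores).
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = TRUE)
  load_ens <- function(files) {
    members <- lapply(file.path(dir, files), read_network)
    structure(list(members = members, mode = "loaded", pool = members),
              class = "bturn_ensemble")
  }
  first <- list()
  second <- list()
  for (key in names(manifest$ensembles)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ens <- load_ens(manifest$ensembles[[key]])
    if (parts[1] == "first") first[[parts[2]]] <- ens
    else second[[parts[2]]] <- ens
  }
  structure(list(first = first, second = second, setup = manifest$setup,
                 plan = tibble::as_tibble(manifest$plan),
                 threshold = manifest$threshold, types = manifest$types,
                 seed = manifest$seed, labels = NULL, cv_first = NULL,
                 cv_second = NULL),
            class = "bturn_model")
}
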