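# Plain-text serialization of fitted MDM decoders (prototypes, reference,
# feature configuration), so a replay is reproducible from the file alone.

.write_matrix_block <- function(con, name, M) {
  writeLines(sprintf("[%s]", name), con)
  writeLines(apply(M, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                            collapse = " ")), con)
}

#' Save an MDM model as a structured text file
#'
#' @param model an `mdm_model` from [mdm_fit()].
#' @param path output path.
#' @param config optional named list of feature configuration (estimator,
#'   scale, trace_norm, ...) stored verbatim.
#' @export
write_model <- function(model, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dccabci mdm model", con)
  writeLines(paste("classes:", paste(model$classes, collapse = " ")), con)
  for (k in names(config))
    writeLines(paste0(k, ": ", paste(config[[k]], collapse = " ")), con)
  for (cl in model$classes)
    .write_matrix_block(con, paste0("prototype ", cl), model$prototypes[[cl]])
  if (!is.null(model$reference))
    .write_matrix_block(con, "reference", model$reference)
  invisible(path)
}

#' Load an MDM model saved by [write_model()]
#'
#' @param path model file path.
#' @return list with `model` (an `mdm_model`) and `config` (named character
#'   list of the stored feature configuration).
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  is_hdr <- grepl("^\\[", lines)
  kv <- lines[!is_hdr & grepl(":", lines) & cumsum(is_hdr) == 0]
  config <- list()
  for (l in kv) {
    k <- trimws(sub(":.*", "", l))
    v <- strsplit(trimws(sub("^[^:]*:", "", l)), " +")[[1L]]
    config[[k]] <- v
  }
  classes <- config$classes
  config$classes <- NULL
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\[", lines[i])) {
      name <- gsub("^\\[|\\]$", "", lines[i])
      j <- i + 1L
      while (j <= length(lines) && !grepl("^\\[", lines[j])) j <- j + 1L
      rows <- lapply(lines[(i + 1L):(j - 1L)], function(r)
        as.numeric(strsplit(trimws(r), " +")[[1L]]))
      blocks[[name]] <- do.call(rbind, rows)
      i <- j
    } else i <- i + 1L
  }
  prototypes <- lapply(classes, function(cl) blocks[[paste0("prototype ", cl)]])
  names(prototypes) <- classes
  model <- structure(list(prototypes = prototypes, classes = classes,
                          reference = blocks[["reference"]]),
                     class = "mdm_model")
  list(model = model, config = config)
}
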