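#' Read gene sets from a GMT file
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes duplicated within a
#' line are removed.
#'
#' @param path path to a GMT file.
#' @return A `GeneSetCollection`: named list of character vectors, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ptc("ptc_io", "GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_ptc("ptc_format", "empty GMT file: %s", path)
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop_ptc("ptc_format", "GMT line %d has fewer than 3 fields", i)
    nms[i] <- fields[1L]
    descs[i] <- fields[2L]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  names(sets) <- nms
  names(descs) <- nms
  ptc_log("read_gmt: %d sets, %d genes total", length(sets),
          length(unique(unlist(sets))))
  structure(sets, descriptions = descs, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x),
              paste(head(lengths(x), 5), collapse = ", ")))
  invisible(x)
}
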