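#' Construct a gene-set collection
#'
#' A collection is a named list of character vectors of gene symbols, with a
#' parallel vector of free-text descriptions stored as an attribute. Member
#' symbols are whitespace-stripped and de-duplicated (first occurrence wins);
#' comparisons throughout the package are case-sensitive.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector, one per set.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == "")))
    stop_fmt("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop_fmt("duplicate set names: %s",
             paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(sets) == 0))
    stop_fmt("empty gene set(s): %s",
             paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets))
    stop_fmt("need one description per set")
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' GMT is the community standard: one tab-separated line per set with fields
#' name, description, then member genes.
#'
#' @param path file path.
#' @return `gene_set_collection`, preserving file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_fmt("'%s' line %d: GMT lines need name, description and >= 1 gene",
             path, which(nf < 3)[1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions") %||% rep("", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[[i]], collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' Used for reference sets such as GO_RESPONSE_TO_OXIDATIVE_STRESS exported
#' as a flat list. Blank lines and surrounding whitespace are dropped.
#'
#' @param path file path.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path))
  unique(g[nzchar(g)])
}
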