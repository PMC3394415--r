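# GRAPPA-style genome files: a ">name" header line followed by one line of
# whitespace-separated signed integers per genome. All genomes are circular.

#' Read genomes from a GRAPPA-style file
#'
#' @param path File path. Lines starting with \code{>} name the following
#'   genome; the gene order may span a single line. A lone \code{@} token
#'   (circularity marker in some dialects) is tolerated and dropped.
#' @return Named list of [genome()] objects.
#' @export
read_genomes <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  nm <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      nm <- trimws(sub("^>", "", ln))
    } else {
      toks <- strsplit(ln, "[[:space:]]+")[[1L]]
      toks <- toks[toks != "@"]
      if (!length(toks)) next
      if (is.null(nm)) nm <- paste0("genome", length(out) + 1L)
      out[[nm]] <- genome(as.integer(toks), name = nm)
      nm <- NULL
    }
  }
  out
}

#' Write genomes to a GRAPPA-style file
#'
#' Emits the canonical writing of each genome.
#'
#' @param genomes Named list of [genome()] objects.
#' @param path Output file path.
#' @export
write_genomes <- function(genomes, path) {
  nms <- names(genomes)
  if (is.null(nms)) nms <- vapply(genomes, function(g) g$name, "")
  nms[!nzchar(nms)] <- paste0("genome", which(!nzchar(nms)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(genomes)) {
    g <- canonical_genome(genomes[[i]])
    writeLines(c(paste0(">", nms[i]), paste(g$genes, collapse = " ")), con)
  }
  invisible(path)
}

#' Read a list of adjacencies given as signed gene pairs
#'
#' Each non-empty line holds two signed integers \code{a b}, meaning gene
#' \code{a} immediately followed by gene \code{b} (see
#' [gene_pair_adjacency()]).
#'
#' @param path File path.
#' @return Two-column matrix of extremity vertices.
#' @export
read_adjacency_pairs <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- t(vapply(lines, function(ln) {
    ab <- as.integer(strsplit(ln, "[[:space:]]+")[[1L]])
    if (length(ab) != 2L || anyNA(ab)) stop("malformed adjacency line: ", ln)
    gene_pair_adjacency(ab[1L], ab[2L])
  }, integer(2L)))
  dimnames(out) <- list(NULL, c("u", "v"))
  out
}
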