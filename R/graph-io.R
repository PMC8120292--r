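#' Canonical serialization of a labeled mixed graph
#'
#' Produces a string key that is identical for two graphs with the same
#' labeled node set, kinds, and edge set (including orientation state),
#' regardless of the order in which nodes are stored. Used to count uniquely
#' inferred graphs in node-ordering stability experiments.
#'
#' @param x a [CausalGraph-class].
#' @return a single character string.
#' @examples
#' g <- basicModelGraph("M1")
#' canonicalForm(g)
#' @rdname canonicalForm
#' @export
setMethod("canonicalForm", "CausalGraph", function(x) {
  labs <- x@labels
  if (anyDuplicated(labs)) stop("duplicate node labels")
  ord <- order(labs)
  A <- x@adj[ord, ord, drop = FALSE]
  labs <- labs[ord]
  kinds <- x@kinds[ord]
  edges <- character()
  p <- length(labs)
  if (p >= 2) {
    for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
      st <- .edgeState(A, i, j)
      if (st == 0L) next
      edges <- c(edges,
                 switch(st,
                        paste0(labs[i], ">", labs[j]),   # 1: i -> j
                        paste0(labs[j], ">", labs[i]),   # 2: j -> i
                        paste0(labs[i], "--", labs[j]))) # 3: undirected
    }
  }
  paste0(paste(labs, substr(kinds, 1, 1), sep = ":", collapse = ";"),
         "|", paste(sort(edges), collapse = ";"))
})

#' Read a samples-by-variables data matrix
#'
#' Delimited text with a header row of variable names. Genotype
#' (instrumental-variable) columns come first, followed by phenotype columns,
#' so kinds are assigned positionally from \code{nGenotypes}.
#'
#' @param path file path.
#' @param nGenotypes number of leading genotype columns (0 for purely
#'   phenotypic data, in which case PMR orientation is a no-op).
#' @param sep field separator (default tab).
#' @return list with \code{data} (numeric matrix), \code{labels}, and
#'   \code{kinds}.
#' @export
readDataMatrix <- function(path, nGenotypes = 0, sep = "\t") {
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0) stop("no data rows in ", path)
  if (nGenotypes > ncol(df))
    stop("nGenotypes (", nGenotypes, ") exceeds column count (",
         ncol(df), ") in ", path)
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, colnames(df)))
  for (k in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[k]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value '", df[[k]][bad], "' at row ", bad,
           ", column '", colnames(df)[k], "' of ", path)
    }
    m[, k] <- v
  }
  kinds <- rep("phenotype", ncol(m))
  if (nGenotypes > 0) kinds[seq_len(nGenotypes)] <- "genotype"
  list(data = m, labels = colnames(m), kinds = kinds)
}

#' Write a graph to file
#'
#' \code{adjacency-tsv} writes the labeled 0/1 parent-by-child matrix with a
#' \code{#kinds:} comment line so kinds survive a round trip; \code{dot}
#' writes Graphviz DOT with directed edges as arrows, undirected
#' (symmetric) pairs as a single edge with \code{dir=none}, genotype nodes
#' as filled triangles and phenotype nodes as filled circles.
#'
#' @param g a [CausalGraph-class].
#' @param path output path.
#' @param format \code{"adjacency-tsv"} or \code{"dot"}.
#' @seealso [readGraph()]
#' @export
writeGraph <- function(g, path, format = c("adjacency-tsv", "dot")) {
  format <- match.arg(format)
  if (format == "adjacency-tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#kinds: ", paste(g@kinds, collapse = "\t")), con)
    writeLines(paste(c("node", g@labels), collapse = "\t"), con)
    for (i in seq_along(g@labels))
      writeLines(paste(c(g@labels[i], g@adj[i, ]), collapse = "\t"), con)
  } else {
    labs <- g@labels
    q <- function(x) paste0("\"", x, "\"")
    lines <- c("digraph causal {")
    shapes <- ifelse(g@kinds == "genotype", "triangle", "circle")
    lines <- c(lines, paste0("  ", q(labs), " [shape=", shapes,
                             ", style=filled];"))
    p <- length(labs)
    if (p >= 2) {
      for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
        st <- .edgeState(g@adj, i, j)
        if (st == 0L) next
        lines <- c(lines,
                   switch(st,
                          paste0("  ", q(labs[i]), " -> ", q(labs[j]), ";"),
                          paste0("  ", q(labs[j]), " -> ", q(labs[i]), ";"),
                          paste0("  ", q(labs[i]), " -> ", q(labs[j]),
                                 " [dir=none];")))
      }
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a graph written in the adjacency-tsv dialect
#'
#' @param path file written by [writeGraph()] with
#'   \code{format = "adjacency-tsv"}.
#' @return a [CausalGraph-class].
#' @export
readGraph <- function(path) {
  first <- readLines(path, n = 1)
  kinds <- NULL
  skip <- 0
  if (startsWith(first, "#kinds:")) {
    kinds <- strsplit(sub("^#kinds:\\s*", "", first), "\t", fixed = TRUE)[[1]]
    skip <- 1
  }
  df <- read.table(path, header = TRUE, sep = "\t", skip = skip,
                   check.names = FALSE)
  labs <- as.character(df[[1]])
  A <- as.matrix(df[, -1, drop = FALSE])
  dimnames(A) <- list(labs, colnames(df)[-1])
  if (is.null(kinds)) kinds <- rep("phenotype", length(labs))
  causalGraph(A, kinds = kinds, labels = labs)
}
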