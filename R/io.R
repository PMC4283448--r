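#' Write per-OTU aligned FASTA files
#'
#' One file per OTU (`<otu>.fasta`), read IDs formatted
#' `<otu>|<site>|<serial>`; gap is `-`, missing coverage `.`.
#'
#' @param read_sets list of `aligned_read_set`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
write_alignments <- function(read_sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(read_sets, function(rs) {
    seqs <- apply(rs$reads, 1, paste0, collapse = "")
    x <- Biostrings::BStringSet(seqs)
    names(x) <- rownames(rs$reads)
    path <- file.path(dir, paste0(rs$otu_id, ".fasta"))
    Biostrings::writeXStringSet(x, path, width = 80L)
    path
  }, character(1))
  invisible(paths)
}

#' Read per-OTU aligned FASTA files
#'
#' Reads every `*.fasta` in `dir`; record IDs must parse as
#' `<otu>|<site>|<serial>` and all records of a file must share one aligned
#' length.
#'
#' @param dir directory of aligned FASTA files.
#' @return named list of `aligned_read_set`.
#' @export
read_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) {
    warning("no FASTA files found in ", dir)
    return(list())
  }
  out <- lapply(files, function(f) {
    x <- Biostrings::readBStringSet(f)
    w <- Biostrings::width(x)
    if (length(unique(w)) != 1L)
      stop("format error: ragged alignment in ", basename(f),
           " at record ", names(x)[which(w != w[1])[1]])
    ids <- strsplit(names(x), "|", fixed = TRUE)
    bad <- lengths(ids) != 3L
    if (any(bad))
      stop("labeling error: unparseable read ID ", names(x)[which(bad)[1]],
           " in ", basename(f))
    reads <- matrix(unlist(strsplit(as.character(x), "", fixed = TRUE), use.names = FALSE),
                    nrow = length(x), byrow = TRUE)
    rownames(reads) <- names(x)
    structure(list(otu_id = ids[[1]][1], reads = reads,
                   site_of_read = vapply(ids, `[`, character(1), 2),
                   taxonomy = NULL),
              class = "aligned_read_set")
  })
  names(out) <- vapply(out, `[[`, character(1), "otu_id")
  out
}

#' Write / read a tab-separated table
#'
#' @param x data.frame or matrix (matrices gain a leading id column).
#' @param path file path.
#' @return `read_tsv_file` returns a data.frame.
#' @export
write_tsv_file <- function(x, path) {
  if (is.matrix(x))
    x <- data.frame(id = rownames(x), as.data.frame(x), check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @export
read_tsv_file <- function(path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)

#' Export an association graph
#'
#' Writes GraphML (node/edge attributes preserved) and a SIF-style edge
#' list TSV (`node1`, `node2`, `ia`, `p`, `p_adjusted`).
#'
#' @param g igraph graph from [build_graph()].
#' @param graphml_path,edges_path output paths (NULL to skip either).
#' @return invisibly, the written paths.
#' @export
export_graph <- function(g, graphml_path = NULL, edges_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(g)
    ne <- nrow(el)
    grab <- function(a) {
      v <- igraph::edge_attr(g, a)
      if (is.null(v)) rep(NA_real_, ne) else v
    }
    df <- data.frame(node1 = el[, 1], node2 = el[, 2],
                     ia = grab("weight"), p = grab("p"),
                     p_adjusted = grab("p_adjusted"))
    write_tsv_file(df, edges_path)
    written <- c(written, edges_path)
  }
  invisible(written)
}
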