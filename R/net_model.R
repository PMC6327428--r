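#' Construct a bipartite lncRNA-protein interaction network
#'
#' Container for a binary bipartite network between a set of long non-coding
#' RNAs and a set of RNA-binding proteins. The adjacency matrix holds a 1
#' where an interaction between `lncrna_ids[i]` and `protein_ids[j]` is known
#' and 0 otherwise; its rows are the lncRNA association profiles and its
#' columns the protein association profiles.
#'
#' @param adjacency n x m matrix with entries in \{0, 1\}; rows are lncRNAs,
#'   columns are proteins.
#' @param lncrna_ids character vector of n unique lncRNA identifiers.
#'   Defaults to the row names of `adjacency`, or `L1..Ln` when absent.
#' @param protein_ids character vector of m unique protein identifiers.
#'   Defaults to the column names of `adjacency`, or `P1..Pm` when absent.
#'
#' @return An object of class `interaction_network`: a list with elements
#'   `lncrna_ids`, `protein_ids` and `adjacency` (a labelled numeric matrix).
#' @examples
#' net <- interaction_network(matrix(c(1, 0, 1, 1), 2, 2),
#'                            c("L1", "L2"), c("P1", "P2"))
#' net
#' @export
interaction_network <- function(adjacency,
                                lncrna_ids = rownames(adjacency),
                                protein_ids = colnames(adjacency)) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  n <- nrow(adjacency)
  m <- ncol(adjacency)
  if (n < 1L || m < 1L) {
    stop("an interaction network needs at least one lncRNA and one protein")
  }
  if (is.null(lncrna_ids)) lncrna_ids <- paste0("L", seq_len(n))
  if (is.null(protein_ids)) protein_ids <- paste0("P", seq_len(m))
  lncrna_ids <- as.character(lncrna_ids)
  protein_ids <- as.character(protein_ids)
  if (length(lncrna_ids) != n) {
    stop("length of 'lncrna_ids' (", length(lncrna_ids),
         ") does not match the number of adjacency rows (", n, ")")
  }
  if (length(protein_ids) != m) {
    stop("length of 'protein_ids' (", length(protein_ids),
         ") does not match the number of adjacency columns (", m, ")")
  }
  if (anyDuplicated(lncrna_ids)) stop("duplicate lncRNA identifiers")
  if (anyDuplicated(protein_ids)) stop("duplicate protein identifiers")
  if (anyNA(adjacency) || !all(adjacency == 0 | adjacency == 1)) {
    stop("adjacency entries must be exactly 0 or 1")
  }
  dimnames(adjacency) <- list(lncrna_ids, protein_ids)
  structure(
    list(lncrna_ids = lncrna_ids, protein_ids = protein_ids,
         adjacency = adjacency),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$lncrna_ids), "lncRNAs x",
      length(x$protein_ids), "proteins,", sum(x$adjacency),
      "known interactions\n")
  invisible(x)
}

edge_sep <- function(dialect) if (dialect == "csv") "," else "\t"

# Split one edge-list line into fields. TSV accepts runs of tabs or spaces
# so hand-written fixtures with space-separated pairs parse too.
split_fields <- function(line, dialect) {
  if (dialect == "csv") {
    strsplit(line, ",", fixed = TRUE)[[1]]
  } else {
    strsplit(trimws(line), "[ \t]+")[[1]]
  }
}

parse_id_header <- function(line, prefix) {
  body <- sub(prefix, "", line, fixed = TRUE)
  ids <- strsplit(trimws(body), "[,\t ]+")[[1]]
  ids[nzchar(ids)]
}

#' Read a bipartite edge list
#'
#' Parses a two-column edge-list file (lncRNA id, protein id) into an
#' [interaction_network()]. Lines starting with `#` are comments, except the
#' optional header lines `#lncrnas: id1,id2,...` and `#proteins: ...`, which
#' declare identifiers up front so that isolated nodes (all-zero rows or
#' columns) survive a round trip. Duplicate pairs collapse to a single edge
#' with a warning; a third column, if present, is ignored with a warning
#' (the network is unweighted). Identifiers are ordered by first appearance,
#' header declarations first.
#'
#' @param path path to the edge-list file.
#' @param dialect `"tsv"` (tab- or space-separated, default) or `"csv"`.
#' @return An [interaction_network()].
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lnc_declared <- character()
  prot_declared <- character()
  edges <- matrix(character(), 0, 2)
  warned_weight <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      if (startsWith(line, "#lncrnas:")) {
        lnc_declared <- c(lnc_declared, parse_id_header(line, "#lncrnas:"))
      } else if (startsWith(line, "#proteins:")) {
        prot_declared <- c(prot_declared, parse_id_header(line, "#proteins:"))
      }
      next
    }
    fields <- split_fields(line, dialect)
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop("malformed edge-list line ", ln, " in '", path,
           "': expected at least 2 fields, got ", length(fields))
    }
    if (length(fields) > 2L && !warned_weight) {
      warning("extra columns in '", path,
              "' ignored: the interaction network is unweighted")
      warned_weight <- TRUE
    }
    edges <- rbind(edges, fields[1:2])
  }
  if (nrow(edges) == 0L && !(length(lnc_declared) && length(prot_declared))) {
    stop("no edges and no id headers in '", path, "'")
  }
  if (anyDuplicated(edges)) {
    warning(sum(duplicated(edges)), " duplicate pair(s) in '", path,
            "' collapsed")
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  lnc_ids <- unique(c(lnc_declared, edges[, 1]))
  prot_ids <- unique(c(prot_declared, edges[, 2]))
  adj <- matrix(0, length(lnc_ids), length(prot_ids),
                dimnames = list(lnc_ids, prot_ids))
  if (nrow(edges) > 0L) adj[edges] <- 1
  interaction_network(adj, lnc_ids, prot_ids)
}

#' Write a bipartite edge list
#'
#' Inverse of [read_edge_list()]: writes `#lncrnas:` / `#proteins:` header
#' lines (so identifier order and isolated nodes round-trip exactly) followed
#' by one line per interacting pair.
#'
#' @param net an [interaction_network()].
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(net, "interaction_network"))
  sep <- edge_sep(dialect)
  idx <- which(net$adjacency == 1, arr.ind = TRUE)
  lines <- c(
    paste0("#lncrnas: ", paste(net$lncrna_ids, collapse = ",")),
    paste0("#proteins: ", paste(net$protein_ids, collapse = ","))
  )
  if (nrow(idx) > 0L) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    lines <- c(lines, paste(net$lncrna_ids[idx[, 1]],
                            net$protein_ids[idx[, 2]], sep = sep))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a dense labelled adjacency matrix
#'
#' CSV with protein identifiers as column header and lncRNA identifiers in
#' the first column.
#'
#' @param path CSV file path.
#' @return An [interaction_network()].
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  interaction_network(as.matrix(df), rownames(df), colnames(df))
}

#' Write a dense labelled adjacency matrix
#'
#' @param net an [interaction_network()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(net, path) {
  utils::write.csv(as.data.frame(net$adjacency), path)
  invisible(path)
}

#' Association profiles
#'
#' The lncRNA association profile of lncRNA i is row i of the adjacency
#' matrix — its binary interaction vector over all proteins. The protein
#' association profile of protein j is column j. These profiles are the
#' points that ant-colony clustering and linear neighborhood similarity
#' operate on.
#'
#' @param net an [interaction_network()].
#' @return A labelled binary matrix, one profile per row: n x m for
#'   `lncrna_profiles()`, m x n for `protein_profiles()`.
#' @export
lncrna_profiles <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  net$adjacency
}

#' @rdname lncrna_profiles
#' @export
protein_profiles <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  t(net$adjacency)
}
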