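#' Read a genes x cells expression matrix
#'
#' Reads a CSV in the common benchmark layout: the first column holds gene
#' identifiers, the header row holds cell identifiers, and each remaining
#' entry is the (typically log-scale) expression of one gene in one cell.
#' Row and column order of the file are preserved exactly.
#'
#' @param path Path to the expression CSV.
#' @param impute_zeros If `TRUE`, missing entries (`NA`/`NaN`) are replaced
#'   with 0, the usual dropout convention for single-cell data. By default
#'   missing values are an error, so data problems are not silently hidden.
#' @return A numeric matrix with genes as rows (rownames = gene ids) and
#'   cells as columns (colnames = cell ids).
#' @export
load_expression <- function(path, impute_zeros = FALSE) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("expression file must have a gene-id column plus at least one cell column")
  }
  genes <- trimws(as.character(raw[[1L]]))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    stop("duplicated gene names in ", path, ": ", paste(dup, collapse = ", "))
  }
  cells <- trimws(colnames(raw)[-1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1L], is.numeric, logical(1L)))
    stop("non-numeric expression values in column(s): ",
         paste(cells[bad], collapse = ", "))
  }
  dimnames(vals) <- list(genes, cells)
  if (anyNA(vals)) {
    if (impute_zeros) {
      vals[is.na(vals)] <- 0
    } else {
      idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing expression value at gene '", genes[idx[1L]], "', cell '",
           cells[idx[2L]], "'; use impute_zeros = TRUE to replace with 0")
    }
  }
  if (any(!is.finite(vals))) {
    stop("non-finite expression values in ", path)
  }
  vals
}

#' Write an expression matrix in the same CSV dialect read by [load_expression()]
#'
#' @param expr Numeric matrix, genes x cells, with dimnames.
#' @param path Output CSV path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell pseudotime table
#'
#' Expects a CSV whose first column holds cell identifiers and whose
#' remaining columns hold pseudotime values: either a single `PseudoTime`
#' (or `Time`) column, or one `PseudoTime1`, `PseudoTime2`, ... column per
#' trajectory. A cell belongs to trajectory k when its entry in column k is
#' non-missing; cells on several trajectories appear once per trajectory.
#'
#' @param path Path to the pseudotime CSV.
#' @param expr Optional companion expression matrix; every one of its cells
#'   must be covered by the table.
#' @return A data frame with columns `cell`, `t`, `trajectory` (integer,
#'   from the time-column index), ordered by trajectory then file order.
#' @export
load_pseudotime <- function(path, expr = NULL) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("pseudotime file needs a cell-id column and at least one time column")
  }
  cells <- trimws(as.character(raw[[1L]]))
  tcols <- which(grepl("^(PseudoTime|Time)[0-9]*$", colnames(raw)))
  if (length(tcols) == 0L) tcols <- 2L
  pieces <- lapply(seq_along(tcols), function(k) {
    tv <- suppressWarnings(as.numeric(raw[[tcols[k]]]))
    keep <- !is.na(tv)
    if (!any(keep)) return(NULL)
    data.frame(cell = cells[keep], t = tv[keep], trajectory = k,
               stringsAsFactors = FALSE)
  })
  pt <- do.call(rbind, pieces)
  if (is.null(pt) || nrow(pt) == 0L) stop("no usable pseudotime values in ", path)
  if (any(!is.finite(pt$t))) stop("non-finite pseudotime values in ", path)
  if (!is.null(expr)) {
    missing_cells <- setdiff(colnames(expr), pt$cell)
    if (length(missing_cells) > 0L) {
      stop("cells missing from pseudotime table: ",
           paste(missing_cells, collapse = ", "))
    }
  }
  rownames(pt) <- NULL
  pt
}

#' Write a pseudotime table in the dialect read by [load_pseudotime()]
#'
#' One `PseudoTime<k>` column per trajectory (a single trajectory is written
#' as plain `PseudoTime`); cells absent from a trajectory get empty entries.
#'
#' @param pt Data frame with columns `cell`, `t`, `trajectory`.
#' @param path Output CSV path.
#' @export
write_pseudotime <- function(pt, path) {
  trajs <- sort(unique(pt$trajectory))
  cells <- unique(pt$cell)
  out <- data.frame(cells, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- ""
  for (k in trajs) {
    sub <- pt[pt$trajectory == k, ]
    col <- rep(NA_real_, length(cells))
    col[match(sub$cell, cells)] <- sub$t
    nm <- if (length(trajs) == 1L) "PseudoTime" else paste0("PseudoTime", k)
    out[[nm]] <- col
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a directed edge list (prior, reference, or inferred network)
#'
#' Expects a CSV with header `Gene1,Gene2` and optionally a `Type` column
#' (a `+`/`-` regulation sign, stored but ignored by inference and
#' evaluation, which are unsigned) and/or a numeric `score` column.
#'
#' @param path Path to the edge CSV.
#' @param allow_self_loops If `FALSE` (default) self-loop rows are skipped
#'   with a warning rather than kept.
#' @return A data frame with columns `regulator`, `target` and, when
#'   present in the file, `score` and `sign`, in file order.
#' @export
load_edge_list <- function(path, allow_self_loops = FALSE) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("edge file needs at least two columns (Gene1,Gene2)")
  edges <- data.frame(regulator = trimws(as.character(raw[[1L]])),
                      target = trimws(as.character(raw[[2L]])),
                      stringsAsFactors = FALSE)
  nm <- tolower(colnames(raw))
  if ("score" %in% nm) edges$score <- as.numeric(raw[[which(nm == "score")[1L]]])
  if ("type" %in% nm) edges$sign <- trimws(as.character(raw[[which(nm == "type")[1L]]]))
  if (!allow_self_loops) {
    loops <- edges$regulator == edges$target
    if (any(loops)) {
      warning("skipping ", sum(loops), " self-loop edge(s), e.g. ",
              edges$regulator[which(loops)[1L]])
      edges <- edges[!loops, , drop = FALSE]
    }
  }
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate edge in ", path, ": (", d$regulator, ", ", d$target, ")")
  }
  rownames(edges) <- NULL
  edges
}

#' Write a directed edge list in the dialect read by [load_edge_list()]
#'
#' Scores, when present, are written with 6 decimal places.
#'
#' @param edges Data frame with columns `regulator`, `target` and optional
#'   `score`, `sign`.
#' @param path Output CSV path.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(Gene1 = edges$regulator, Gene2 = edges$target,
                    stringsAsFactors = FALSE)
  if (!is.null(edges$sign)) out$Type <- edges$sign
  if (!is.null(edges$score)) out$score <- sprintf("%.6f", edges$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
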