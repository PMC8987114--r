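# Readers and writers for the tabular formats the pipeline touches:
# expression matrices, binary trait tables, GMT gene sets, and
# Cytoscape-ready edge lists / GraphML.

#' Read a gene-by-sample expression matrix
#'
#' Reads a TSV or CSV table (gene identifiers in the first column, sample
#' identifiers in the header) into a numeric matrix with gene rownames and
#' sample colnames. Values are expected on a log-like scale; the reader does
#' no normalisation. Non-numeric cells are treated as missing and handled by
#' `na_policy`; duplicate gene rows are collapsed by their mean with a
#' warning.
#'
#' @param path Path to a `.tsv`/`.txt` (tab-separated) or `.csv` file.
#' @param na_policy Either `"drop_gene"` (default; any gene with a missing
#'   value after parsing is removed) or `"impute_row_mean"` (missing cells
#'   replaced by the gene's mean over observed samples).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, na_policy = c("drop_gene", "impute_row_mean")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", colClasses = "character")
  if (ncol(raw) < 3) {
    stop("expression table needs a gene column plus at least 2 samples: ", path)
  }
  samples <- colnames(raw)[-1]
  if (!anyNA(suppressWarnings(as.numeric(samples)))) {
    stop("header looks numeric; expression file seems to be missing its header row: ",
         path)
  }
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample ids in ", path, ": ", paste(dup_s, collapse = ", "))
  }
  genes <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[vals %in% c("", "NA", "na", "NaN")] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  # any cell that failed numeric coercion is missing from here on
  bad <- is.na(num)
  dimnames(num) <- list(genes, samples)
  if (any(bad)) {
    n_bad <- sum(rowSums(bad) > 0)
    if (na_policy == "drop_gene") {
      keep <- rowSums(bad) == 0
      warning(sprintf("dropping %d gene(s) with missing/non-numeric cells", n_bad))
      num <- num[keep, , drop = FALSE]
    } else {
      all_na <- rowSums(bad) == ncol(num)
      if (any(all_na)) {
        stop("gene(s) with no numeric value at all: ",
             paste(rownames(num)[all_na], collapse = ", "))
      }
      warning(sprintf("imputing row means for %d gene(s) with missing cells", n_bad))
      rm_ <- rowMeans(num, na.rm = TRUE)
      idx <- which(bad, arr.ind = TRUE)
      num[idx] <- rm_[idx[, 1L]]
    }
  }
  if (anyDuplicated(rownames(num))) {
    dup_g <- unique(rownames(num)[duplicated(rownames(num))])
    warning(sprintf("collapsing %d duplicated gene id(s) by mean: %s",
                    length(dup_g), paste(dup_g, collapse = ", ")))
    num <- rowsum(num, group = rownames(num), reorder = FALSE) /
      as.vector(table(rownames(num))[unique(rownames(num))])
  }
  validate_expression(num, where = path)
  num
}

# shared invariants for an expression matrix
validate_expression <- function(x, where = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(where, ": not a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop(where, ": need at least 2 genes and 2 samples")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(where, ": gene and sample identifiers required")
  }
  if (anyDuplicated(rownames(x))) stop(where, ": duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop(where, ": duplicate sample ids")
  if (!all(is.finite(x))) stop(where, ": non-finite values present")
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; round-trips values to better than 1e-9.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary trait table aligned to an expression matrix
#'
#' Expects two columns (sample id, label in \{0, 1\}; 1 = disease/case,
#' 0 = control), with or without a header line. The returned vector is
#' reordered to the expression matrix's sample order.
#'
#' @param path Path to the two-column TSV/CSV.
#' @param expr Expression matrix the traits must align to.
#' @return Named integer vector of 0/1 labels in `colnames(expr)` order.
#' @export
read_traits <- function(path, expr) {
  validate_expression(expr)
  if (!file.exists(path)) stop("trait file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- length(first) >= 2L && !first[2L] %in% c("0", "1")
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("trait table needs two columns (sample, label): ", path)
  ids <- tab[[1L]]
  lab <- tab[[2L]]
  bad_lab <- !lab %in% c("0", "1")
  if (any(bad_lab)) {
    stop("trait labels must be 0 or 1; offending value(s): ",
         paste(unique(lab[bad_lab]), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in trait file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing_tr <- setdiff(colnames(expr), ids)
  extra_tr <- setdiff(ids, colnames(expr))
  if (length(missing_tr) || length(extra_tr)) {
    stop("trait/expression sample mismatch;",
         if (length(missing_tr)) paste0(" missing from traits: ",
                                        paste(missing_tr, collapse = ", ")),
         if (length(extra_tr)) paste0(" absent from matrix: ",
                                      paste(extra_tr, collapse = ", ")))
  }
  out <- as.integer(lab)[match(colnames(expr), ids)]
  names(out) <- colnames(expr)
  validate_traits(out)
  out
}

# both classes present with >= 4 samples each (Fisher z needs n - 3 > 0)
validate_traits <- function(traits) {
  if (!all(traits %in% c(0L, 1L))) stop("trait labels must be 0/1")
  n1 <- sum(traits == 1L)
  n0 <- sum(traits == 0L)
  if (n1 < 4L || n0 < 4L) {
    stop(sprintf(paste0("each condition needs >= 4 samples ",
                        "(got %d cases, %d controls); Fisher's z requires n - 3 > 0"),
                 n1, n0))
  }
  invisible(traits)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT v2: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member lists are
#' deduplicated; empty sets are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; set descriptions are kept in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 tab-separated fields")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(lengths(members) == 0L)
  if (length(empty)) {
    stop("GMT set(s) with empty member list: ", paste(nm[empty], collapse = ", "))
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(members) <- nm
  names(desc) <- nm
  attr(members, "description") <- desc
  members
}

#' Export a differential-correlation network for Cytoscape
#'
#' Writes the switched/significant pair records either as a flat edge TSV
#' (columns `source, target, r_cond1, r_cond2, p_diff, lfdr, sign_switch`)
#' or as GraphML with the same six edge attributes.
#'
#' @param records Data frame of differential-correlation records, as
#'   returned by [diffcorr_scan()] or [switched_pairs()].
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @export
write_network <- function(records, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  need <- c("gene_a", "gene_b", "r1", "r2", "p_diff", "lfdr", "switched")
  if (!all(need %in% names(records))) {
    stop("records must contain columns: ", paste(need, collapse = ", "))
  }
  edges <- data.frame(
    source = records$gene_a,
    target = records$gene_b,
    r_cond1 = records$r1,
    r_cond2 = records$r2,
    p_diff = records$p_diff,
    lfdr = records$lfdr,
    sign_switch = ifelse(records$switched, "true", "false"),
    stringsAsFactors = FALSE
  )
  if (format == "edge_tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(edges) == 0L) stop("graphml export needs at least one record")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
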