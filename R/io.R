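# readers/writers for the pipeline's plain-text formats: TSV tables, gas CSV,
# Newick trees. UTF-8, '.' decimal throughout.

#' Read / write a biogeochemical table (TSV)
#'
#' @param file Path to a tab-separated file.
#' @return A tibble.
#' @export
read_biogeochem <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE)
  if (anyDuplicated(out$composite_id)) {
    abort("duplicated composite ids.", class = "mfsoil_schema")
  }
  out
}

#' @rdname read_biogeochem
#' @param data Tibble to write.
#' @export
write_biogeochem <- function(data, file) {
  readr::write_tsv(data, file)
  invisible(file)
}

#' Read an OTU table (TSV)
#'
#' Native orientation is OTUs-as-rows: a header of sample ids, one row per
#' OTU (`otu_id` first column), an optional trailing `taxonomy` column.
#' `orientation = "samples"` accepts the transposed layout (samples as
#' rows).
#'
#' @param file Path to a tab-separated file.
#' @param orientation `"otus"` (rows are OTUs, default) or `"samples"`.
#' @return Wide OTU tibble (`composite_id` + integer columns) with the
#'   `taxonomy` attribute when present.
#' @export
read_otu_table <- function(file, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(file, show_col_types = FALSE)
  if (orientation == "samples") {
    m <- df_to_matrix(raw, names(raw)[1])
    out <- bind_cols(tibble(composite_id = rownames(m)), as_tibble(m))
  } else {
    tax <- NULL
    if ("taxonomy" %in% names(raw)) {
      tax <- tibble(otu_id = as.character(raw[[1]]), taxonomy = raw$taxonomy)
      raw$taxonomy <- NULL
    }
    m <- t(df_to_matrix(raw, names(raw)[1]))
    out <- bind_cols(tibble(composite_id = rownames(m)), as_tibble(m))
    attr(out, "taxonomy") <- tax
  }
  if (any(as.matrix(out[-1]) < 0)) {
    abort("negative counts in OTU table.", class = "mfsoil_schema")
  }
  out
}

#' @rdname read_otu_table
#' @param data Wide OTU tibble.
#' @export
write_otu_table <- function(data, file, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  if (orientation == "samples") {
    readr::write_tsv(data, file)
  } else {
    m <- otu_counts(data)
    out <- bind_cols(tibble(otu_id = colnames(m)),
                     as_tibble(t(m)))
    tax <- attr(data, "taxonomy")
    if (!is.null(tax)) {
      out$taxonomy <- tax$taxonomy[match(out$otu_id, tax$otu_id)]
    }
    readr::write_tsv(out, file)
  }
  invisible(file)
}

#' Read a long gas time-series table (CSV)
#'
#' Expected columns: `sample_id`, `gas`, `time_h`, `ppmv`.
#'
#' @param file Path to a comma-separated file.
#' @return A tibble.
#' @export
read_gas_series <- function(file) {
  out <- readr::read_csv(file, show_col_types = FALSE)
  need <- c("sample_id", "gas", "time_h", "ppmv")
  if (!all(need %in% names(out))) {
    abort(paste0("gas series needs columns: ", paste(need, collapse = ", ")),
          class = "mfsoil_schema")
  }
  out
}

#' @rdname read_gas_series
#' @param data Tibble to write.
#' @export
write_gas_series <- function(data, file) {
  readr::write_csv(data, file)
  invisible(file)
}

quote_newick_label <- function(x) {
  ifelse(grepl("[][():;,'\"[:space:]]", x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Write a UPGMA tree as Newick with node p-values as comments
#'
#' Branch lengths follow the merge-height convention (a leaf under a node
#' at height h gets branch length h); SIMPROF p-values, when supplied, are
#' embedded as `[p=...]` comments on internal nodes. Labels containing
#' structural characters are single-quoted.
#'
#' @param tree An `hclust` tree.
#' @param file Output path; `NULL` returns the string.
#' @param node_p Optional numeric vector of p-values indexed by merge node.
#' @return The Newick string, invisibly when written to file.
#' @export
write_tree_newick <- function(tree, file = NULL, node_p = NULL) {
  h <- tree$height
  nwk <- function(node, parent_h) {
    if (node < 0) {
      paste0(quote_newick_label(tree$labels[-node]), ":",
             format(parent_h, digits = 10))
    } else {
      kids <- paste(nwk(tree$merge[node, 1], h[node]),
                    nwk(tree$merge[node, 2], h[node]), sep = ",")
      cmt <- if (!is.null(node_p) && !is.na(node_p[node])) {
        paste0("[p=", format(node_p[node], digits = 4), "]")
      } else ""
      paste0("(", kids, ")", cmt, ":",
             format(parent_h - h[node], digits = 10))
    }
  }
  root <- length(h)
  kids <- paste(nwk(tree$merge[root, 1], h[root]),
                nwk(tree$merge[root, 2], h[root]), sep = ",")
  cmt <- if (!is.null(node_p) && !is.na(node_p[root])) {
    paste0("[p=", format(node_p[root], digits = 4), "]")
  } else ""
  out <- paste0("(", kids, ")", cmt, ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}
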