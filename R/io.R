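#' Read a feature-by-sample abundance matrix
#'
#' Reads a TSV/CSV matrix (features as rows, first column feature ids, header
#' row of sample ids) into an [omics_block()]. Non-numeric cells become `NA`.
#'
#' @param path Path to the matrix file. Separator is taken from the extension
#'   (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param ome_label Ome name attached to the block.
#' @param metadata_path Optional path to a TSV/CSV with columns `sample_id`,
#'   `start_date`, `end_date` giving each sample's collection window.
#' @param sep Optional field separator override.
#' @param transposed Set `TRUE` only if the file is samples-by-features;
#'   orientation is never guessed.
#'
#' @return An [omics_block()].
#' @export
read_omics_matrix <- function(path, ome_label, metadata_path = NULL,
                              sep = NULL, transposed = FALSE) {
  sep <- sep %||% infer_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs an id column plus >=1 sample: ", path)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicated feature ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "character"
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  if (transposed) num <- t(num)
  sw <- NULL
  if (!is.null(metadata_path)) {
    sw <- utils::read.table(metadata_path, sep = infer_sep(metadata_path),
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    extra <- setdiff(colnames(num), sw$sample_id)
    if (length(extra) > 0) {
      stop("metadata in ", metadata_path, " lacks samples: ",
           paste(extra, collapse = ", "))
    }
  }
  omics_block(num, ome_label, sample_windows = sw)
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an omics block matrix to TSV
#'
#' Missing values are serialized as `NA`; the first column (`feature_id`)
#' holds the feature ids. [read_omics_matrix()] round-trips the file.
#'
#' @param block An [omics_block()].
#' @param path Output path.
#' @export
write_omics_matrix <- function(block, path) {
  chr <- matrix(fmt_full(block$values), nrow(block$values),
                dimnames = dimnames(block$values))
  df <- data.frame(feature_id = rownames(block$values), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# 17 significant digits: doubles survive the text round-trip bit-exactly
fmt_full <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' Read pathway sets from a GMT file
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. The description is kept
#' but ignored by computations; duplicate members on a line are deduplicated.
#'
#' @param path Path to a GMT file.
#' @return A named list of pathway sets; each element is a list with
#'   `pathway_id`, `pathway_name`, `description`, and a character vector
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(list(), character()))
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields in ", path)
    }
    out[[i]] <- list(pathway_id = f[[1]], pathway_name = f[[1]],
                     description = f[[2]], members = unique(f[-(1:2)]))
  }
  ids <- vapply(out, `[[`, character(1), "pathway_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicated pathway ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  stats::setNames(out, ids)
}

#' Read an adduct table
#'
#' TSV with columns `adduct_name`, `mass_shift` (Da), `charge` (signed,
#' non-zero), `polarity` (`+` or `-`).
#'
#' @param path Path to the TSV.
#' @return Data frame with the four validated columns.
#' @export
read_adduct_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_adduct_table(df)
}

validate_adduct_table <- function(df) {
  req <- c("adduct_name", "mass_shift", "charge", "polarity")
  if (!all(req %in% names(df))) {
    stop("adduct table needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(df) == 0) stop("adduct table is empty")
  dup <- unique(df$adduct_name[duplicated(df$adduct_name)])
  if (length(dup) > 0) stop("duplicated adducts: ", paste(dup, collapse = ", "))
  if (any(df$charge == 0)) stop("adduct charge must be non-zero")
  if (!all(df$polarity %in% c("+", "-"))) stop("polarity must be '+' or '-'")
  df[, req]
}

#' Default electrospray adduct table
#'
#' Common positive-mode ([M+H]+, [M+Na]+, [M+NH4]+) and negative-mode
#' ([M-H]-, [M+CH3COO]-, [M+Cl]-) singly charged adducts with their mass
#' shifts in Da.
#'
#' @return Data frame in the [read_adduct_table()] layout.
#' @export
default_adducts <- function() {
  data.frame(
    adduct_name = c("[M+H]+", "[M+Na]+", "[M+NH4]+",
                    "[M-H]-", "[M+CH3COO]-", "[M+Cl]-"),
    mass_shift = c(1.007276, 22.989218, 18.033823,
                   -1.007276, 59.013851, 34.968853),
    charge = c(1L, 1L, 1L, -1L, -1L, -1L),
    polarity = c("+", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE
  )
}

#' Read a metabolic network from an edge list
#'
#' Builds an undirected simple metabolite graph from a two-column edge list
#' (TSV, header `from`/`to` or first two columns) and a metabolite-to-mass
#' table (`metabolite_id`, `monoisotopic_mass`). Self-loops and duplicate
#' edges are dropped with a message; metabolites present in edges but absent
#' from the mass table are kept with unknown (NA) mass and excluded from
#' adduct matching.
#'
#' @param path Edge list TSV.
#' @param masses_path Mass table TSV.
#' @return A `metabolic_network` object; see [metabolic_network()].
#' @export
read_metabolic_network <- function(path, masses_path) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge list needs two columns: ", path)
  masses_df <- utils::read.table(masses_path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
  if (ncol(masses_df) < 2) stop("mass table needs two columns: ", masses_path)
  masses <- stats::setNames(as.numeric(masses_df[[2]]),
                            as.character(masses_df[[1]]))
  metabolic_network(edges[, 1:2], masses)
}

#' Construct a metabolic network
#'
#' @param edges Two-column data frame of metabolite id pairs (reactions).
#' @param masses Named numeric vector of monoisotopic masses (Da); nodes
#'   without a mass get `NA` with a warning and are skipped by adduct
#'   matching.
#' @return A `metabolic_network`: list with the igraph `graph`, `masses`,
#'   edge count `m`, and named degree vector `degrees`.
#' @export
metabolic_network <- function(edges, masses) {
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- a == b
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop edge(s)")
    a <- a[!loops]; b <- b[!loops]
  }
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate edge(s)")
    a <- a[!dup]; b <- b[!dup]
  }
  # metabolites with a known mass but no reaction stay as isolated vertices
  nodes <- sort(unique(c(a, b, names(masses))))
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  no_mass <- setdiff(nodes, names(masses))
  if (length(no_mass) > 0) {
    warning("no monoisotopic mass for ", length(no_mass),
            " metabolite(s); excluded from adduct matching: ",
            paste(utils::head(no_mass, 5), collapse = ", "))
  }
  mass_vec <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  known <- intersect(nodes, names(masses))
  mass_vec[known] <- masses[known]
  structure(
    list(graph = g, masses = mass_vec, m = igraph::ecount(g),
         degrees = igraph::degree(g)),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network>", igraph::vcount(x$graph), "metabolites,",
      x$m, "reactions;", sum(is.na(x$masses)), "without mass\n")
  invisible(x)
}

#' Write a correlation network edge table
#'
#' TSV with columns `source`, `source_ome`, `target`, `target_ome`, `rho`,
#' `n_obs`, `p`, `q`, rows sorted by (source, target) so repeated runs are
#' byte-identical. An empty network yields a header-only file.
#'
#' @param network A `correlation_network` from [build_network()].
#' @param path Output path.
#' @export
write_edge_table <- function(network, path) {
  ed <- network$edges
  ed <- ed[order(ed$source, ed$target), , drop = FALSE]
  for (col in c("rho", "p", "q")) ed[[col]] <- fmt_full(ed[[col]])
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path Path to the TSV.
#' @return A `correlation_network` (edges plus recomputed degrees).
#' @export
read_edge_table <- function(path) {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  new_correlation_network(ed)
}

#' Export a correlation network as GraphML
#'
#' @param network A `correlation_network`.
#' @param path Output path (.graphml).
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
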