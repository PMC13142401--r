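## Readers and writers for every tabular format the pipeline touches.
## All tables are UTF-8, decimal point, tab- or comma-separated by
## extension; readers validate headers and invariants and fail loudly.

BGC_CLASSES <- c("NRPS", "PKS", "RiPP", "terpene", "hybrid", "other")

#' Describe a similarity-network file dialect
#'
#' BiG-SCAPE `.network` files are tab-separated with the two node columns
#' first and a "Raw distance" column; a minimal 3-column layout (node,
#' node, distance, any header) is also accepted via `dialect = "minimal"`.
#'
#' @param node_a,node_b,distance Column names holding the two BGC ids and
#'   the raw distance.
#' @return A `network_dialect` list.
#' @export
network_dialect <- function(node_a = "Clustername 1",
                            node_b = "Clustername 2",
                            distance = "Raw distance") {
  structure(list(node_a = node_a, node_b = node_b, distance = distance),
            class = "network_dialect")
}

resolve_dialect <- function(dialect) {
  if (inherits(dialect, "network_dialect")) return(dialect)
  check_that(is.character(dialect) && length(dialect) == 1L,
             "dialect must be a network_dialect object, \"bigscape\" or \"minimal\"")
  switch(dialect,
         bigscape = network_dialect(),
         minimal = structure(list(node_a = NA, node_b = NA, distance = NA),
                             class = c("minimal_dialect", "network_dialect")),
         stop(sprintf("unknown network dialect '%s'", dialect), call. = FALSE))
}

#' Read a BGC similarity network file
#'
#' Parses a tab-separated edge list of pairwise BGC distances. Self-loops
#' are dropped and duplicate (unordered) pairs are collapsed keeping the
#' minimum distance.
#'
#' @param path File path.
#' @param dialect A [network_dialect()], `"bigscape"` (default) or
#'   `"minimal"` (first three columns by position).
#' @return `data.frame` with columns `a`, `b`, `distance`.
#' @export
read_network <- function(path, dialect = "bigscape") {
  check_that(file.exists(path), "network file not found: %s", path)
  dialect <- resolve_dialect(dialect)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (inherits(dialect, "minimal_dialect")) {
    check_that(ncol(tab) >= 3L,
               "minimal network dialect needs >= 3 columns, found %d", ncol(tab))
    tab <- tab[, 1:3]
    names(tab) <- c("a", "b", "distance")
  } else {
    for (fld in c("node_a", "node_b", "distance")) {
      col <- dialect[[fld]]
      check_that(col %in% names(tab),
                 "network file lacks dialect column '%s' (dialect field %s)",
                 col, fld)
    }
    tab <- data.frame(a = as.character(tab[[dialect$node_a]]),
                      b = as.character(tab[[dialect$node_b]]),
                      distance = tab[[dialect$distance]],
                      stringsAsFactors = FALSE)
  }
  tab$distance <- as.numeric(tab$distance)
  bad <- which(!is.finite(tab$distance) | tab$distance < 0 | tab$distance > 1)
  if (length(bad)) {
    stop(sprintf("distance outside [0,1] at row %d of %s", bad[1], path),
         call. = FALSE)
  }
  canonicalize_edges(tab)
}

# Order endpoints, drop self-loops, collapse duplicate pairs keeping the
# minimum distance. Shared by read_network and build_network.
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(a = character(), b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  a <- as.character(edges$a)
  b <- as.character(edges$b)
  lev <- c_sort(unique(c(a, b))) # C-collation endpoint ordering
  swap <- match(a, lev) > match(b, lev)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- a != b
  out <- data.frame(a = a[keep], b = b[keep],
                    distance = as.numeric(edges$distance[keep]),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1L) {
    out <- out[c_order(out$a, out$b, out$distance), , drop = FALSE]
    key <- paste(out$a, out$b, sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a similarity network file
#'
#' @param edges `data.frame` with columns `a`, `b`, `distance`.
#' @param path Output path.
#' @param dialect As in [read_network()]; `"minimal"` writes plain
#'   `a`/`b`/`distance` headers.
#' @export
write_network <- function(edges, path, dialect = "bigscape") {
  dialect <- resolve_dialect(dialect)
  out <- edges[, c("a", "b", "distance"), drop = FALSE]
  out$distance <- sprintf("%.17g", out$distance) # exact double round-trip
  if (!inherits(dialect, "minimal_dialect")) {
    names(out) <- c(dialect$node_a, dialect$node_b, dialect$distance)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-sample BGC inventory table
#'
#' Expects a tab-separated file with header `bgc_id`, `sample_id`,
#' `bgc_class`. Class labels are normalized case-insensitively to
#' NRPS/PKS/RiPP/terpene/hybrid/other; unrecognized labels map to
#' `"other"` with one summarising warning.
#'
#' @param path File path.
#' @return `data.frame` with `bgc_id`, `sample_id`, `bgc_class`,
#'   `is_reference` (id matches the reference pattern).
#' @param reference_pattern Regular expression identifying reference
#'   (MIBiG-style) accessions; default `"^BGC\\d{7}"`.
#' @export
read_inventory <- function(path, reference_pattern = "^BGC\\d{7}") {
  check_that(file.exists(path), "inventory file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bgc_id", "sample_id", "bgc_class")
  miss <- setdiff(need, names(tab))
  check_that(length(miss) == 0L,
             "inventory lacks required column(s): %s", paste(miss, collapse = ", "))
  tab$bgc_id <- as.character(tab$bgc_id)
  dup <- tab$bgc_id[duplicated(tab$bgc_id)]
  check_that(length(dup) == 0L, "duplicate bgc_id in inventory: %s", dup[1])
  tab$bgc_class <- normalize_bgc_class(tab$bgc_class)
  tab$is_reference <- grepl(reference_pattern, tab$bgc_id)
  tab[, c("bgc_id", "sample_id", "bgc_class", "is_reference")]
}

#' Normalize biosynthetic class labels
#'
#' @param x Character vector of raw class labels.
#' @return Factor-free character vector over the six canonical labels;
#'   unknown labels become `"other"` with a single warning giving the count.
#' @export
normalize_bgc_class <- function(x) {
  x <- as.character(x)
  idx <- match(tolower(x), tolower(BGC_CLASSES))
  n_unknown <- sum(is.na(idx) & !is.na(x))
  if (n_unknown > 0L) {
    warning(sprintf("%d inventory class label(s) not recognized; mapped to 'other'",
                    n_unknown), call. = FALSE)
    gcf_log(sprintf("unrecognized class labels mapped to other: n=%d", n_unknown))
  }
  out <- BGC_CLASSES[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Write a BGC inventory table
#' @param inventory `data.frame` with `bgc_id`, `sample_id`, `bgc_class`.
#' @param path Output path (TSV).
#' @export
write_inventory <- function(inventory, path) {
  utils::write.table(inventory[, c("bgc_id", "sample_id", "bgc_class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ENV_COLUMNS <- c("sample_id", "temperature", "pH", "conductivity",
                 "crustal_thickness", "sequencing_depth",
                 "tectonic_setting", "volcanic_province")

#' Read a sample metadata table
#'
#' Comma-separated, one row per sample, with environmental and tectonic
#' covariates plus sequencing depth. Enforces unique sample ids, pH in
#' \[0, 14\] and nonnegative sequencing depth.
#'
#' @param path File path (CSV).
#' @return `data.frame` of validated metadata.
#' @export
read_metadata <- function(path) {
  check_that(file.exists(path), "metadata file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(ENV_COLUMNS, names(tab))
  check_that(length(miss) == 0L,
             "metadata lacks required column(s): %s", paste(miss, collapse = ", "))
  validate_metadata(tab)
  tab$tectonic_setting <- as.character(tab$tectonic_setting)
  tab$volcanic_province <- as.character(tab$volcanic_province)
  tab
}

validate_metadata <- function(tab) {
  check_that(!anyDuplicated(tab$sample_id), "duplicate sample_id in metadata")
  check_that(all(tab$pH >= 0 & tab$pH <= 14, na.rm = TRUE),
             "metadata pH outside [0, 14]")
  check_that(all(tab$sequencing_depth >= 0, na.rm = TRUE),
             "metadata sequencing_depth must be >= 0")
  invisible(TRUE)
}

#' Write a sample metadata table
#' @param env Metadata `data.frame` (see [read_metadata()]).
#' @param path Output path (CSV).
#' @export
write_metadata <- function(env, path) {
  validate_metadata(env)
  utils::write.csv(env[, ENV_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CAT-style contig classification table
#'
#' Tab-separated with columns `contig_id`, `sample_id`, `contig_length`,
#' `genus`, `support`. Enforces positive lengths and support in \[0, 1\].
#'
#' @param path File path.
#' @return Validated `data.frame`.
#' @export
read_contigs <- function(path) {
  check_that(file.exists(path), "contig table not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "sample_id", "contig_length", "genus", "support")
  miss <- setdiff(need, names(tab))
  check_that(length(miss) == 0L,
             "contig table lacks required column(s): %s",
             paste(miss, collapse = ", "))
  check_that(all(tab$contig_length > 0), "contig_length must be > 0")
  check_that(all(tab$support >= 0 & tab$support <= 1),
             "contig support must lie in [0, 1]")
  tab
}

#' Write a contig classification table
#' @param contigs `data.frame` as returned by [read_contigs()].
#' @param path Output path (TSV).
#' @export
write_contigs <- function(contigs, path) {
  utils::write.table(contigs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a samples-by-features matrix as TSV
#'
#' First column `sample_id` holds row names; remaining columns are
#' features. Round-trips exactly with [read_matrix()].
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  check_that(!is.null(rownames(m)) && !is.null(colnames(m)),
             "matrix must carry row and column names")
  fm <- apply(m, 2, function(col) sprintf("%.17g", col)) # exact round-trip
  if (!is.matrix(fm)) fm <- matrix(fm, nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(sample_id = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples-by-features matrix written by [write_matrix()]
#' @param path File path.
#' @return Numeric matrix with sample row names.
#' @export
read_matrix <- function(path) {
  check_that(file.exists(path), "matrix file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_that(names(df)[1] == "sample_id", "matrix file must start with sample_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$sample_id
  m
}

#' Serialize analysis results with provenance
#'
#' Writes a JSON file whose `provenance` block records the package
#' version, the seed in effect, and a hash of the configuration, so every
#' reported number is traceable.
#'
#' @param results Named list of results (must be JSON-representable).
#' @param path Output path.
#' @param seed Seed used to produce the results.
#' @param config Optional configuration object hashed into provenance.
#' @export
write_results_json <- function(results, path, seed, config = NULL) {
  prov <- list(
    package = "geoGCF",
    version = as.character(utils::packageVersion("geoGCF")),
    seed = as.integer(seed),
    config_hash = if (is.null(config)) NA_character_ else
      content_hash(deparse(config))
  )
  jsonlite::write_json(list(provenance = prov, results = results), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a key:value configuration file into a simulation config
#'
#' One `key: value` pair per line; `#` starts a comment. List-valued keys
#' (classes, distance intervals) are comma-separated. Unknown keys error.
#'
#' @param path File path.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  check_that(file.exists(path), "config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  check_that(length(bad) == 0L, "cannot parse config line: '%s'", lines[bad[1]])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  args <- list()
  numeric_keys <- c("n_samples", "n_families_per_class", "ref_fraction",
                    "cutoff", "effect_size", "depth_bias", "noise_sd",
                    "ct_known_bias", "base_detect", "depth_meanlog",
                    "depth_sdlog", "n_genera", "taxonomy_coupling", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% c("classes")) {
      args[[k]] <- trimws(strsplit(v, ",")[[1]])
    } else if (k %in% c("within_family_distance", "cross_family_distance")) {
      args[[k]] <- as.numeric(trimws(strsplit(v, ",")[[1]]))
    } else if (k %in% numeric_keys) {
      args[[k]] <- as.numeric(v)
    } else {
      stop(sprintf("unknown config key '%s'", k), call. = FALSE)
    }
  }
  do.call(sim_config, args)
}

#' Write a simulation config as a key:value file
#' @param config A [sim_config()] object.
#' @param path Output path.
#' @export
write_sim_config <- function(config, path) {
  fmt <- function(v) paste(v, collapse = ", ")
  keys <- setdiff(names(config), "settings")
  lines <- vapply(keys, function(k) sprintf("%s: %s", k, fmt(config[[k]])), "")
  writeLines(lines, path)
  gcf_log("config written: ", paste(lines, collapse = " | "))
  invisible(path)
}
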