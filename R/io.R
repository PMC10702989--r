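#' Read / write subject-by-feature tables
#'
#' Plain-CSV serialization used for feature tables, genotype code tables and
#' network matrices alike: first column `subject_id` (or the row entity's
#' id), remaining columns numeric, header row with feature labels. Reading
#' returns a numeric matrix with ids as rownames.
#'
#' @param path File path.
#' @return `read_feature_table()`: numeric matrix with rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed table (need id column plus data): ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(df[-1L], is.numeric, logical(1L))]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' @rdname read_feature_table
#' @param x Numeric matrix with subject ids as rownames.
#' @param id_col Name of the id column (default `"subject_id"`).
#' @export
write_feature_table <- function(x, path, id_col = "subject_id") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("matrix must carry ids as rownames")
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read diagnosis labels aligned to a subject ordering
#'
#' Reads a two-column CSV (`subject_id`, `label`). When `subject_ids` is
#' given, rows are re-aligned to that ordering by id (never by row order);
#' missing or unknown ids are an error.
#'
#' @param path File path.
#' @param subject_ids Optional character vector defining the ordering.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path, subject_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% colnames(df))) {
    stop("labels file must have columns subject_id and label: ", path)
  }
  labs <- stats::setNames(as.character(df$label), as.character(df$subject_id))
  if (!is.null(subject_ids)) {
    missing <- setdiff(subject_ids, names(labs))
    if (length(missing)) {
      stop("labels missing for subject(s): ", paste(missing, collapse = ", "))
    }
    labs <- labs[subject_ids]
  }
  labs
}

#' @rdname read_labels
#' @param labels Named character vector (names = subject ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(subject_id = names(labels),
                              label = as.character(labels)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Additive 0/1/2 encoding of biallelic genotype calls
#'
#' Per SNP, alleles are ranked by frequency: homozygous-major maps to 0,
#' heterozygous to 1, homozygous-minor to 2. A 50/50 allele tie is broken
#' toward the lexicographically smaller allele as major. Heterozygote
#' strings are order-insensitive ("AG" and "GA" both code 1). Missing calls
#' (`NA` or empty) yield `NA` codes; the per-SNP drop count is reported in
#' the `"n_missing"` attribute.
#'
#' @param calls Character matrix/data frame, subjects x SNPs, entries like
#'   `"AG"`.
#' @return Integer matrix of 0/1/2 codes (NA where the call was missing)
#'   with attributes `"major_allele"`, `"minor_allele"`, `"n_missing"`.
#' @export
#' @examples
#' encode_additive(matrix(c("AA", "AA", "AG"), ncol = 1,
#'                        dimnames = list(NULL, "rs1")))
encode_additive <- function(calls) {
  calls <- as.matrix(calls)
  n_snp <- ncol(calls)
  snp_ids <- colnames(calls)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(n_snp))
  codes <- matrix(NA_integer_, nrow(calls), n_snp,
                  dimnames = list(rownames(calls), snp_ids))
  major <- minor <- character(n_snp)
  n_missing <- integer(n_snp)
  for (s in seq_len(n_snp)) {
    x <- as.character(calls[, s])
    miss <- is.na(x) | x == ""
    n_missing[s] <- sum(miss)
    obs <- x[!miss]
    if (any(nchar(obs) != 2L)) stop("malformed genotype call at SNP ", snp_ids[s])
    al <- unlist(strsplit(obs, ""))
    tab <- table(al)
    if (length(tab) > 2L) {
      stop("more than 2 alleles at SNP ", snp_ids[s], ": ",
           paste(names(tab), collapse = ", "))
    }
    alleles <- names(sort(tab, decreasing = TRUE))
    if (length(alleles) == 2L && tab[[alleles[1L]]] == tab[[alleles[2L]]]) {
      alleles <- sort(alleles)  # tie: lexicographically smaller allele is major
    }
    maj <- alleles[1L]
    min_al <- if (length(alleles) == 2L) alleles[2L] else NA_character_
    major[s] <- maj
    minor[s] <- if (is.na(min_al)) "" else min_al
    cnt <- integer(length(x))
    cnt[!miss] <- (substr(obs, 1, 1) != maj) + (substr(obs, 2, 2) != maj)
    cnt[miss] <- NA_integer_
    codes[, s] <- cnt
  }
  attr(codes, "major_allele") <- stats::setNames(major, snp_ids)
  attr(codes, "minor_allele") <- stats::setNames(minor, snp_ids)
  attr(codes, "n_missing") <- stats::setNames(n_missing, snp_ids)
  codes
}

#' Import a PLINK-style additive dosage export
#'
#' Reads a tab-separated text export with one row per subject, first column
#' the subject id, remaining columns 0/1/2 dosages (missing cells allowed).
#'
#' @param path File path.
#' @return Numeric matrix, subjects x SNPs, NAs preserved.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage values outside {0,1,2} in ", path)
  rownames(m) <- ids
  m
}

#' Serialize a subject network as sparse triplets
#'
#' Writes the nonzero entries of a subject-by-subject network as a
#' tab-separated `i, j, weight` triplet table (ids when available).
#'
#' @param W N x N matrix, `"sen"` or `"fusion_network"` object.
#' @param path Output path.
#' @export
write_network_triplets <- function(W, path) {
  if (inherits(W, "sen") || inherits(W, "fusion_network")) W <- W$W
  idx <- which(W != 0, arr.ind = TRUE)
  ids <- rownames(W)
  df <- data.frame(
    i = if (is.null(ids)) idx[, 1L] else ids[idx[, 1L]],
    j = if (is.null(ids)) idx[, 2L] else ids[idx[, 2L]],
    weight = W[idx]
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a structured run configuration
#'
#' Reads a YAML configuration covering the cross-validation, simulation and
#' solver keys and merges it over the package defaults; unknown keys are an
#' error so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- list(
    outer_folds = 5L, inner_folds = 5L, repeats = 5L,
    lambda_grid = default_lambda_grid(), seed = 1L,
    integration = "MM", network = "FSN",
    test_reconstruction = "sparse_code_on_train",
    sen_lambda = NULL, fuse_iter = 10L, fuse_tol = 1e-6,
    fit_tol = 1e-9, fit_max_iter = 2000L,
    n_per_class = c(64L, 78L, 29L), d = 116L, M = 2L,
    subspace_dim = 4L, support_size = 6L, effect_size = 1,
    noise_sd_features = 0.5, noise_sd_response = 0.5,
    response_mode = "additive_012"
  )
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, user)
}

#' Write a run manifest beside pipeline outputs
#'
#' Records the configuration, seed and package version of a run so outputs
#' are reproducible from the manifest alone.
#'
#' @param config Configuration list.
#' @param seed Integer seed used.
#' @param path Output YAML path.
#' @export
write_manifest <- function(config, seed, path) {
  yaml::write_yaml(list(
    package = "senfuse",
    version = as.character(utils::packageVersion("senfuse")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  ), path)
  invisible(path)
}
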