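# Readers and writers for the plain-text formats the pipeline exchanges:
# gene-by-sample TSVs, gene sets (GMT or one-per-line), homolog maps,
# trait tables, and the synthetic-truth JSON.

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#'
#' @param path File path.
#' @return Numeric gene-by-sample matrix.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a gene-by-sample expression TSV
#'
#' @param values Numeric matrix with gene row names and sample column names.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_expression <- function(values, path) {
  values <- check_matrix(values, min_samples = 1)
  df <- tibble::as_tibble(values, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read gene sets from GMT or one-ID-per-line text
#'
#' GMT lines are `name<TAB>description<TAB>member...`; a file whose lines
#' hold a single token is read as one unnamed set (named after the file).
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(fields) == 1)) {
    out <- list(vapply(fields, `[[`, character(1), 1))
    names(out) <- tools::file_path_sans_ext(basename(path))
    return(out)
  }
  if (any(lengths(fields) < 3)) {
    stop("GMT lines need name, description and at least one member", call. = FALSE)
  }
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- vapply(fields, `[[`, character(1), 1)
  out
}

#' Read a two-column homolog map TSV
#'
#' @param path File path; columns `id_a`, `id_b` (header required).
#' @return A tibble `id_a`, `id_b`.
#' @export
read_homologs <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1:2] <- c("id_a", "id_b")
  tibble::as_tibble(df[, 1:2])
}

#' Read a sample-by-trait TSV
#'
#' @param path File path; first column sample ID.
#' @return A tibble whose first column is `sample`.
#' @export
read_traits <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1] <- "sample"
  tibble::as_tibble(df)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `exprA.tsv`, `exprB.tsv`, optional `traits.tsv` and
#' `species.tsv`, and `truth.json` (the simulation spec and planted-pair
#' table, round-trippable with [read_truth()]).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$expr_a, file.path(dir, "exprA.tsv"))
  write_expression(dataset$expr_b, file.path(dir, "exprB.tsv"))
  if (!is.null(dataset$traits)) {
    readr::write_tsv(dataset$traits, file.path(dir, "traits.tsv"))
  }
  if (!is.null(dataset$species_b)) {
    write_expression(dataset$species_b, file.path(dir, "species.tsv"))
  }
  spec <- dataset$truth$spec
  truth <- list(
    spec = list(
      n_genes = spec$n_genes,
      n_per_condition = spec$n_per_condition,
      blocks = lapply(spec$blocks, unclass),
      hubs = lapply(spec$hubs, unclass),
      de_genes = spec$de_genes,
      batch_effects = as.list(spec$batch_effects),
      noise_sd = spec$noise_sd, mean_sd = spec$mean_sd,
      transform = spec$transform, seed = spec$seed
    ),
    pairs = dataset$truth$pairs,
    species_pairs = dataset$truth$species_pairs,
    species_divergence = dataset$truth$species_divergence
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back the truth of a written synthetic dataset
#'
#' @param dir Directory written by [write_dataset()].
#' @return A list with the reconstructed `spec` ([sim_spec()]) and the
#'   planted `pairs` tibble.
#' @export
read_truth <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  s <- raw$spec
  mk_list <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  }
  spec <- sim_spec(
    n_genes = s$n_genes,
    n_per_condition = s$n_per_condition,
    blocks = lapply(mk_list(s$blocks), function(b) {
      block_spec(unlist(b$genes), b$rho_a, b$rho_b)
    }),
    hubs = lapply(mk_list(s$hubs), function(h) {
      hub_spec(h$hub, unlist(h$partners), h$rho_a, h$rho_b)
    }),
    de_genes = s$de_genes,
    batch_effects = if (length(s$batch_effects)) unlist(s$batch_effects) else NULL,
    noise_sd = s$noise_sd, mean_sd = s$mean_sd,
    transform = s$transform, seed = s$seed
  )
  list(spec = spec, pairs = tibble::as_tibble(raw$pairs))
}

nrow_or_zero <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
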