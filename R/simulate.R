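#' Specify a block of equicorrelated genes
#'
#' A block is a stand-in for a co-regulated gene cluster: every pair of genes
#' inside it shares the same latent (Gaussian-scale) correlation, possibly
#' different between the two conditions. Note that the *Spearman* correlation
#' observed downstream converges to `(6 / pi) * asin(rho / 2)`, not to `rho`
#' itself (the Gaussian-copula rank attenuation).
#'
#' @param genes Integer vector of gene indices (disjoint from all other
#'   blocks and hubs in the same [sim_spec()]).
#' @param rho_a,rho_b Latent correlation in condition A / condition B, each in
#'   (-1, 1). An m-gene equicorrelation matrix is positive definite only for
#'   `rho > -1/(m - 1)`; violations are rejected.
#' @return A `block_spec` object.
#' @export
#' @examples
#' block_spec(1:10, rho_a = 0.6, rho_b = 0.6)
block_spec <- function(genes, rho_a, rho_b) {
  genes <- sort(unique(as.integer(genes)))
  if (length(genes) < 2) stop("a block needs at least 2 genes", call. = FALSE)
  for (rho in c(rho_a, rho_b)) {
    if (!is.numeric(rho) || abs(rho) >= 1) {
      stop("block rho must lie in (-1, 1)", call. = FALSE)
    }
    if (rho <= -1 / (length(genes) - 1)) {
      stop("block of size ", length(genes), " with rho = ", rho,
           " is not positive definite (need rho > -1/(m-1))", call. = FALSE)
    }
  }
  structure(list(genes = genes, rho_a = rho_a, rho_b = rho_b),
            class = "block_spec")
}

#' Specify a hub gene coupled to a partner module
#'
#' Embodies the hub hypothesis: one gene whose co-expression with a set of
#' partners differs between conditions. A literal star correlation matrix
#' (hub-partner `rho`, partners mutually independent) is not positive
#' definite once `m * rho^2 > 1`, so the generator uses a latent-factor
#' construction: the partners load on a shared factor with loading
#' `a = sqrt(max(|rho_a|, |rho_b|))` in *both* conditions (their mutual
#' correlation `a^2` therefore does not change), while the hub couples to
#' the factor with per-condition strength `rho / a`. The hub-partner
#' correlation is exactly `rho_a` / `rho_b`, the differential signal lives
#' only on the hub-partner pairs, and the matrix is positive definite for
#' any partner count.
#'
#' @param hub Integer index of the hub gene.
#' @param partners Integer indices of partner genes (excluding the hub).
#' @param rho_a,rho_b Hub-partner latent correlation per condition, in (-1, 1).
#' @return A `hub_spec` object.
#' @export
#' @examples
#' hub_spec(1, 2:101, rho_a = 0.7, rho_b = 0)
hub_spec <- function(hub, partners, rho_a, rho_b) {
  hub <- as.integer(hub)
  partners <- sort(unique(as.integer(partners)))
  if (length(partners) < 1) stop("a hub needs at least 1 partner", call. = FALSE)
  if (hub %in% partners) stop("hub index cannot be among its partners", call. = FALSE)
  for (rho in c(rho_a, rho_b)) {
    if (!is.numeric(rho) || abs(rho) >= 1) {
      stop("hub rho must lie in (-1, 1)", call. = FALSE)
    }
  }
  structure(list(hub = hub, partners = partners, rho_a = rho_a, rho_b = rho_b),
            class = "hub_spec")
}

#' Specify a two-condition synthetic expression study
#'
#' Collects everything the generator needs: problem size, planted correlation
#' structure (blocks and hubs), mean-shift differentially expressed genes,
#' batch-effect scales, and the global seed. All index sets must be disjoint;
#' every implied correlation matrix is validated at construction.
#'
#' @param n_genes Number of genes.
#' @param n_per_condition Integer pair `c(n_A, n_B)` of sample counts.
#' @param blocks List of [block_spec()] objects.
#' @param hubs List of [hub_spec()] objects.
#' @param de_genes Optional two-column data frame (`gene` index, `lfc` log2
#'   effect) of genes mean-shifted in condition A.
#' @param batch_effects Optional named numeric vector: batch label to
#'   additive per-gene offset scale (sd, >= 0).
#' @param noise_sd Marginal sd of each gene's expression (> 0); correlations
#'   are specified directly, so this is a pure scale.
#' @param mean_sd Sd of per-gene baseline means (log2 scale). Heterogeneous
#'   baselines are what make sample-profile correlations (and cross-species
#'   expression similarity) non-degenerate.
#' @param transform `"none"` (Gaussian values) or `"exp"` (monotone `2^x`
#'   transform mimicking a skewed expression scale; Spearman statistics are
#'   invariant to it).
#' @param seed Global integer seed; expands into per-stage child seeds so
#'   adding a stage never perturbs earlier draws.
#' @return A `sim_spec` object.
#' @export
#' @examples
#' sim_spec(100, c(50, 50), blocks = list(block_spec(1:10, 0.6, 0.6)), seed = 1)
sim_spec <- function(n_genes,
                     n_per_condition = c(100L, 100L),
                     blocks = list(),
                     hubs = list(),
                     de_genes = NULL,
                     batch_effects = NULL,
                     noise_sd = 1,
                     mean_sd = 2,
                     transform = c("none", "exp"),
                     seed = 1L) {
  transform <- match.arg(transform)
  n_genes <- as.integer(n_genes)
  n_per_condition <- as.integer(n_per_condition)
  stopifnot(n_genes >= 1, length(n_per_condition) == 2, all(n_per_condition >= 1))
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (mean_sd < 0) stop("mean_sd must be >= 0", call. = FALSE)

  used <- integer(0)
  claim <- function(idx, what) {
    if (any(idx < 1 | idx > n_genes)) {
      stop(what, " refers to gene indices outside 1..n_genes", call. = FALSE)
    }
    clash <- intersect(idx, used)
    if (length(clash)) {
      stop(what, " overlaps a previously assigned block/hub at gene index ",
           clash[1], call. = FALSE)
    }
    used <<- c(used, idx)
  }
  for (b in blocks) {
    if (!inherits(b, "block_spec")) stop("blocks must be block_spec objects", call. = FALSE)
    claim(b$genes, "block")
  }
  for (h in hubs) {
    if (!inherits(h, "hub_spec")) stop("hubs must be hub_spec objects", call. = FALSE)
    claim(c(h$hub, h$partners), "hub")
  }
  if (!is.null(de_genes)) {
    de_genes <- tibble::as_tibble(as.data.frame(de_genes))
    names(de_genes)[1:2] <- c("gene", "lfc")
    de_genes$gene <- as.integer(de_genes$gene)
    if (any(de_genes$gene < 1 | de_genes$gene > n_genes)) {
      stop("de_genes refers to gene indices outside 1..n_genes", call. = FALSE)
    }
  }
  if (!is.null(batch_effects)) {
    if (is.null(names(batch_effects)) || any(batch_effects < 0)) {
      stop("batch_effects must be a named non-negative numeric vector", call. = FALSE)
    }
  }
  structure(
    list(n_genes = n_genes, n_per_condition = n_per_condition,
         blocks = blocks, hubs = hubs, de_genes = de_genes,
         batch_effects = batch_effects, noise_sd = noise_sd,
         mean_sd = mean_sd, transform = transform, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

gene_ids <- function(spec) sprintf("g%05d", seq_len(spec$n_genes))

# Draw one condition's latent Gaussian matrix (unit marginal variance) with
# the correlation structure implied by the spec's blocks and hubs.
draw_condition <- function(spec, which_rho, n, seed) {
  set.seed(seed)
  g <- spec$n_genes
  x <- matrix(stats::rnorm(g * n), nrow = g, ncol = n)
  for (b in spec$blocks) {
    rho <- b[[which_rho]]
    m <- length(b$genes)
    sigma <- matrix(rho, m, m); diag(sigma) <- 1
    L <- chol(sigma)
    x[b$genes, ] <- crossprod(L, matrix(stats::rnorm(m * n), m, n))
  }
  for (h in spec$hubs) {
    rho <- h[[which_rho]]
    a <- sqrt(max(abs(h$rho_a), abs(h$rho_b)))
    b <- if (a > 0) rho / a else 0
    f <- stats::rnorm(n)
    m <- length(h$partners)
    eps <- matrix(stats::rnorm(m * n), m, n)
    x[h$hub, ] <- b * f + sqrt(1 - b^2) * stats::rnorm(n)
    x[h$partners, ] <- a * rep(f, each = m) + sqrt(1 - a^2) * eps
  }
  x
}

# Enumerate every pair with a planted non-zero latent correlation.
planted_pairs <- function(spec) {
  ids <- gene_ids(spec)
  out <- list()
  for (b in spec$blocks) {
    cmb <- utils::combn(b$genes, 2)
    out[[length(out) + 1]] <- tibble::tibble(
      gene_i = ids[cmb[1, ]], gene_j = ids[cmb[2, ]],
      rho_a = b$rho_a, rho_b = b$rho_b, component = "block"
    )
  }
  for (h in spec$hubs) {
    out[[length(out) + 1]] <- tibble::tibble(
      gene_i = pmin(ids[h$hub], ids[h$partners]),
      gene_j = pmax(ids[h$hub], ids[h$partners]),
      rho_a = h$rho_a, rho_b = h$rho_b, component = "hub"
    )
    if (length(h$partners) > 1) {
      a2 <- max(abs(h$rho_a), abs(h$rho_b))  # shared-factor loading squared
      cmb <- utils::combn(h$partners, 2)
      out[[length(out) + 1]] <- tibble::tibble(
        gene_i = ids[cmb[1, ]], gene_j = ids[cmb[2, ]],
        rho_a = a2, rho_b = a2, component = "hub_partner"
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(gene_i = character(), gene_j = character(),
                          rho_a = numeric(), rho_b = numeric(),
                          component = character()))
  }
  dplyr::bind_rows(out)
}

#' Generate a two-condition expression dataset with planted truth
#'
#' Draws each condition from a multivariate normal with unit-variance
#' correlation structure implied by the spec's blocks and hubs (background
#' pairs exactly independent), scales by `noise_sd`, adds per-gene baseline
#' means, applies the log2 mean shifts of `de_genes` to condition A, and
#' optionally applies a monotone `2^x` transform. Bit-reproducible for a
#' fixed seed.
#'
#' @param spec A [sim_spec()].
#' @return A `synthetic_dataset`: list with gene-by-sample matrices `expr_a`,
#'   `expr_b`, and a `truth` list carrying the spec, the realized gene means,
#'   and the planted pair table (`truth$pairs`: canonical pair keys with the
#'   latent `rho_a`, `rho_b` and component type). Later stages
#'   ([add_clinical_trait()], [add_species_pair()], [add_batch_effects()])
#'   extend the same object.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_spec(50, c(30, 30), seed = 7))
#' dim(ds$expr_a)
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ids <- gene_ids(spec)
  set.seed(child_seed(spec$seed, "means"))
  mu <- stats::rnorm(spec$n_genes, 0, spec$mean_sd)

  n_a <- spec$n_per_condition[1]
  n_b <- spec$n_per_condition[2]
  a <- draw_condition(spec, "rho_a", n_a, child_seed(spec$seed, "cond_a"))
  b <- draw_condition(spec, "rho_b", n_b, child_seed(spec$seed, "cond_b"))
  a <- a * spec$noise_sd + mu
  b <- b * spec$noise_sd + mu
  if (!is.null(spec$de_genes)) {
    a[spec$de_genes$gene, ] <- a[spec$de_genes$gene, ] + spec$de_genes$lfc
  }
  if (spec$transform == "exp") {
    a <- 2^a
    b <- 2^b
  }
  dimnames(a) <- list(ids, sprintf("A%04d", seq_len(n_a)))
  dimnames(b) <- list(ids, sprintf("B%04d", seq_len(n_b)))
  structure(
    list(expr_a = a, expr_b = b,
         truth = list(spec = spec, gene_means = stats::setNames(mu, ids),
                      pairs = planted_pairs(spec)),
         traits = NULL, species_b = NULL, batch = NULL),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$expr_a), " genes; samples A/B = ",
      ncol(x$expr_a), "/", ncol(x$expr_b),
      "; planted pairs = ", nrow(x$truth$pairs), "\n", sep = "")
  if (!is.null(x$traits)) cat("  traits: ", paste(setdiff(names(x$traits), "sample"), collapse = ", "), "\n", sep = "")
  if (!is.null(x$species_b)) cat("  divergent species matrix: ", ncol(x$species_b), " samples\n", sep = "")
  if (!is.null(x$batch)) cat("  batch effects applied\n")
  invisible(x)
}

#' Add a simulated clinical trait coupled to gene expression
#'
#' The trait is a weighted sum of the listed genes' condition-A expression
#' plus Gaussian noise, so the expected Pearson trait-gene correlation is
#' computable in closed form (`w / sqrt(w^2 + sd^2)` for a unit-variance gene
#' with weight `w` and noise sd `sd`).
#'
#' @param dataset A `synthetic_dataset`.
#' @param couplings Two-column data frame (`gene` index or ID, `weight`).
#' @param noise_sd Trait noise sd (>= 0).
#' @param name Trait column name.
#' @param seed Optional integer; defaults to a child of the spec's seed,
#'   offset by the number of traits already present.
#' @return The dataset with `traits` extended (tibble, first column `sample`)
#'   and the couplings recorded in `truth$trait_couplings`.
#' @export
add_clinical_trait <- function(dataset, couplings, noise_sd = 1,
                               name = "trait1", seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  couplings <- tibble::as_tibble(as.data.frame(couplings))
  names(couplings)[1:2] <- c("gene", "weight")
  if (nrow(couplings) == 0) stop("couplings must be non-empty", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ids <- rownames(dataset$expr_a)
  gene <- couplings$gene
  if (is.numeric(gene)) gene <- ids[as.integer(gene)]
  if (any(is.na(gene)) || !all(gene %in% ids)) {
    stop("couplings refer to unknown genes", call. = FALSE)
  }
  n_prev <- if (is.null(dataset$traits)) 0L else ncol(dataset$traits) - 1L
  seed <- seed %||% (child_seed(dataset$truth$spec$seed, "traits") + n_prev)
  set.seed(seed)
  n <- ncol(dataset$expr_a)
  trait <- drop(crossprod(dataset$expr_a[gene, , drop = FALSE], couplings$weight)) +
    stats::rnorm(n, 0, noise_sd)
  if (is.null(dataset$traits)) {
    dataset$traits <- tibble::tibble(sample = colnames(dataset$expr_a))
  }
  dataset$traits[[name]] <- trait
  dataset$truth$trait_couplings <- c(
    dataset$truth$trait_couplings,
    stats::setNames(list(tibble::tibble(gene = gene, weight = couplings$weight,
                                        noise_sd = noise_sd)), name)
  )
  dataset
}

#' Add a second "species" with shared means but divergent co-expression
#'
#' Generates a matrix that shares every gene's baseline mean with the first
#' species while each planted block/hub keeps its condition-A correlation
#' with probability `1 - divergence` and is otherwise re-drawn (sign flip or
#' zero, equal probability). Which components (and hence pairs) were
#' perturbed is recorded in the truth, enabling conservation statistics to be
#' tested against ground truth.
#'
#' @param dataset A `synthetic_dataset`.
#' @param divergence Probability in \\[0, 1\\] that a planted component's
#'   correlation is re-drawn.
#' @param redraw How a perturbed correlation is re-drawn: `"mixed"`
#'   (default; sign flip or zero with equal probability), `"zero"` (lost
#'   co-expression only), or `"flip"` (sign reversal only). `"zero"` makes
#'   conservation decay to independence at divergence 1; `"mixed"`/`"flip"`
#'   additionally create sign-inconsistent pairs.
#' @param n_samples Sample count for the species matrix (default: condition
#'   A's count).
#' @param seed Optional integer; defaults to the spec seed's "species" child.
#' @return The dataset with `species_b` (gene-by-sample matrix) and
#'   `truth$species_pairs` (per planted pair: original latent `rho_a`, the
#'   species' `rho_sp`, and a `perturbed` flag).
#' @export
add_species_pair <- function(dataset, divergence,
                             redraw = c("mixed", "zero", "flip"),
                             n_samples = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  redraw <- match.arg(redraw)
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1) {
    stop("divergence must lie in [0, 1]", call. = FALSE)
  }
  spec <- dataset$truth$spec
  n_samples <- as.integer(n_samples %||% spec$n_per_condition[1])
  seed <- seed %||% child_seed(spec$seed, "species")
  set.seed(seed)

  perturb <- function(rho) {
    if (stats::runif(1) >= divergence) return(list(rho = rho, hit = FALSE))
    new_rho <- switch(redraw,
                      mixed = if (stats::runif(1) < 0.5) -rho else 0,
                      zero = 0,
                      flip = -rho)
    list(rho = new_rho, hit = TRUE)
  }
  sp_spec <- spec
  comp_hit <- logical(0)
  sp_spec$blocks <- lapply(spec$blocks, function(b) {
    p <- perturb(b$rho_a); comp_hit <<- c(comp_hit, p$hit)
    b$rho_a <- p$rho; b
  })
  sp_spec$hubs <- lapply(spec$hubs, function(h) {
    p <- perturb(h$rho_a); comp_hit <<- c(comp_hit, p$hit)
    # the species matrix is drawn from rho_a alone; align rho_b so the
    # partner-module loading reflects the perturbed value only
    h$rho_a <- p$rho; h$rho_b <- p$rho; h
  })

  x <- draw_condition(sp_spec, "rho_a", n_samples, seed + 1L)
  x <- x * spec$noise_sd + dataset$truth$gene_means
  if (spec$transform == "exp") x <- 2^x
  dimnames(x) <- list(gene_ids(spec), sprintf("M%04d", seq_len(n_samples)))
  dataset$species_b <- x

  orig <- planted_pairs(spec)
  sp <- planted_pairs(sp_spec)
  dataset$truth$species_pairs <- tibble::tibble(
    gene_i = orig$gene_i, gene_j = orig$gene_j, component = orig$component,
    rho_a = orig$rho_a, rho_sp = sp$rho_a,
    perturbed = rep(comp_hit, times = tabulate_components(spec))
  )
  dataset$truth$species_divergence <- divergence
  dataset
}

# pairs contributed by each component, in planted_pairs() order
tabulate_components <- function(spec) {
  c(vapply(spec$blocks, function(b) choose(length(b$genes), 2), numeric(1)),
    vapply(spec$hubs, function(h) {
      m <- length(h$partners); m + choose(m, 2)
    }, numeric(1)))
}

#' Add planted batch effects to a synthetic dataset
#'
#' Draws one additive per-gene offset vector per batch (sd from `scale`) and
#' adds it to every sample assigned to that batch, across both condition
#' matrices. Offsets are recorded in the truth so batch correction can be
#' checked exactly: perturbed minus clean equals the recorded offsets.
#'
#' @param dataset A `synthetic_dataset`.
#' @param batches Named character vector: sample ID to batch label, covering
#'   every sample in both conditions.
#' @param scale Named numeric vector: batch label to offset sd (>= 0);
#'   defaults to the spec's `batch_effects`.
#' @param seed Optional integer; defaults to the spec seed's "batch" child.
#' @return The dataset with offsets applied, `batch` set to the assignment,
#'   and `truth$batch_offsets` (gene-by-batch matrix) recorded.
#' @export
add_batch_effects <- function(dataset, batches, scale = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  spec <- dataset$truth$spec
  scale <- scale %||% spec$batch_effects
  if (is.null(scale) || is.null(names(scale))) {
    stop("scale must be a named numeric vector (batch label -> sd)", call. = FALSE)
  }
  samples <- c(colnames(dataset$expr_a), colnames(dataset$expr_b))
  unknown <- setdiff(names(batches), samples)
  if (length(unknown)) {
    stop("unknown sample identifier(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(samples, names(batches))
  if (length(missing)) {
    stop("every sample needs a batch; missing: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  labs <- sort(unique(batches))
  bad <- setdiff(labs, names(scale))
  if (length(bad)) stop("no offset scale for batch ", bad[1], call. = FALSE)

  seed <- seed %||% child_seed(spec$seed, "batch")
  set.seed(seed)
  offsets <- vapply(labs, function(l) stats::rnorm(spec$n_genes, 0, scale[[l]]),
                    numeric(spec$n_genes))
  rownames(offsets) <- rownames(dataset$expr_a)
  add_off <- function(m) m + offsets[, batches[colnames(m)], drop = FALSE]
  dataset$expr_a <- add_off(dataset$expr_a)
  dataset$expr_b <- add_off(dataset$expr_b)
  dataset$batch <- batches
  dataset$truth$batch_offsets <- offsets
  dataset
}

#' Expected Spearman correlation of a bivariate Gaussian pair
#'
#' Rank statistics attenuate a latent Gaussian correlation: the population
#' Spearman correlation is `(6 / pi) * asin(rho / 2)`. Used throughout the
#' tests to convert planted latent correlations into observable targets.
#'
#' @param rho Latent (Pearson, Gaussian-scale) correlation.
#' @return The population Spearman correlation.
#' @export
#' @examples
#' spearman_target(0.6) # ~0.58
spearman_target <- function(rho) (6 / pi) * asin(rho / 2)
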