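#' Specification of a synthetic expression cohort
#'
#' Describes a simulated bulk RNA-seq cohort with known subtype structure:
#' classes of (possibly imbalanced) given sizes, disjoint blocks of marker
#' genes whose log2 mean expression is shifted by `effect_size` in their
#' class, a shared log-normal baseline, per-gene/per-sample Gaussian noise
#' on the log2 scale, per-sample library-size variation, and a zero-inflated
#' gene fraction that the prevalence filter is expected to remove.
#'
#' @param n_genes number of genes.
#' @param class_sizes integer vector of per-class sample counts (all >= 2);
#'   imbalance is allowed and typical.
#' @param markers_per_class marker genes planted per class;
#'   `markers_per_class * length(class_sizes)` must not exceed `n_genes`.
#' @param effect_size log2-scale mean shift added to a class's markers in
#'   that class (>= 0).
#' @param baseline_mean mean of the per-gene baseline log2 expression.
#' @param baseline_sd sd of the per-gene baseline log2 expression.
#' @param noise_sd per-entry log2-scale noise sd (> 0).
#' @param library_size_variation sd of the per-sample log library-size
#'   factor (0 = equal depth).
#' @param zero_inflation fraction of (non-marker) genes subjected to random
#'   dropout.
#' @param dropout_rate per-entry dropout probability for zero-inflated
#'   genes; at the default 0.6 those genes fall below a 75% prevalence
#'   filter with high probability.
#' @param depth expected sequencing depth (total counts) per sample.
#' @param class_names optional class names; default `class_01`, ...
#' @param seed integer seed; generation is deterministic.
#' @return a validated `synth_spec` list.
#' @export
synth_spec <- function(n_genes = 2000L, class_sizes = c(40L, 20L, 10L, 5L),
                       markers_per_class = 20L, effect_size = 2,
                       baseline_mean = 4, baseline_sd = 1.5, noise_sd = 1,
                       library_size_variation = 0.2, zero_inflation = 0.2,
                       dropout_rate = 0.6, depth = 2e6, class_names = NULL,
                       seed = 1L) {
  class_sizes <- as.integer(class_sizes)
  if (any(class_sizes < 2L)) stop("all class sizes must be >= 2", call. = FALSE)
  C <- length(class_sizes)
  if (markers_per_class * C > n_genes)
    stop("markers_per_class * n_classes exceeds n_genes", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (zero_inflation < 0 || zero_inflation >= 1 ||
      dropout_rate < 0 || dropout_rate >= 1)
    stop("zero_inflation and dropout_rate must lie in [0, 1)", call. = FALSE)
  class_names <- class_names %||% sprintf("class_%02d", seq_len(C))
  if (length(class_names) != C || anyDuplicated(class_names))
    stop("class_names must be unique, one per class", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), class_sizes = class_sizes,
                 markers_per_class = as.integer(markers_per_class),
                 effect_size = effect_size, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 library_size_variation = library_size_variation,
                 zero_inflation = zero_inflation, dropout_rate = dropout_rate,
                 depth = depth, class_names = class_names,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Simulate a count matrix with planted subtype structure
#'
#' Generates raw counts so the full preprocessing path (prevalence filter,
#' TPM conversion, log transform) is exercised. Per gene a baseline log2
#' expression is drawn; each class's markers get `+effect_size` in that
#' class; per-entry Gaussian noise is added on the log2 scale; zero-inflated
#' genes are masked by Bernoulli dropout; abundances are converted to
#' Poisson counts at a per-sample library size. The planted marker map and
#' per-gene lengths are returned alongside.
#'
#' @param spec a [synth_spec()].
#' @return list with `expression` (a counts [expression_matrix()]),
#'   `labels` (factor named by sample), `lengths` (named gene-length
#'   vector, bp), and `markers` (list of marker gene ids per class).
#' @export
sim_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  G <- spec$n_genes; C <- length(spec$class_sizes); N <- sum(spec$class_sizes)
  gene_ids <- sprintf("G%05d", seq_len(G))
  sample_ids <- sprintf("S%04d", seq_len(N))
  cls <- rep(spec$class_names, spec$class_sizes)
  with_seed(spec$seed, {
    base <- stats::rnorm(G, spec$baseline_mean, spec$baseline_sd)
    # plant markers on well-expressed genes: marker shifts on dim genes are
    # compressed by TPM normalization and the log transform
    n_mark <- spec$markers_per_class * C
    pool <- order(base, decreasing = TRUE)[seq_len(max(n_mark, G %/% 2))]
    marker_pool <- sample(pool, n_mark)
    markers <- split(marker_pool, rep(seq_len(C), each = spec$markers_per_class))
    mu <- matrix(base, G, N)
    for (ci in seq_len(C))
      mu[markers[[ci]], cls == spec$class_names[ci]] <-
        mu[markers[[ci]], cls == spec$class_names[ci]] + spec$effect_size
    logexpr <- mu + matrix(stats::rnorm(G * N, 0, spec$noise_sd), G, N)
    rel <- 2^logexpr
    if (spec$zero_inflation > 0) {
      n_zi <- floor(spec$zero_inflation * G)
      zi <- sample(setdiff(seq_len(G), marker_pool), n_zi)
      mask <- matrix(stats::rbinom(n_zi * N, 1L, spec$dropout_rate), n_zi, N)
      rel[zi, ][mask == 1L] <- 0
    }
    lib <- exp(stats::rnorm(N, 0, spec$library_size_variation)) * spec$depth
    lambda <- sweep(rel, 2L, colSums(rel), "/")
    lambda <- sweep(lambda, 2L, lib, "*")
    counts <- matrix(stats::rpois(G * N, lambda), G, N,
                     dimnames = list(gene_ids, sample_ids))
    lengths <- stats::setNames(round(stats::runif(G, 200, 10000)), gene_ids)
  })
  names(markers) <- spec$class_names
  list(expression = expression_matrix(counts + 0, "counts"),
       labels = stats::setNames(factor(cls, levels = spec$class_names),
                                sample_ids),
       lengths = lengths,
       markers = lapply(markers, function(i) gene_ids[i]))
}

#' Simulate a cohort with realistic subtype imbalance
#'
#' A desk-scale stand-in for a leukemia subtyping cohort: 20 classes named
#' after the default B-ALL categories ([ball_scheme()]), with the three
#' largest classes at roughly 18.6%, 15.4% and 10.8% of the cohort and the
#' remainder tapering down to rare classes (floor of 5 samples each),
#' about 500 samples and 5,000 genes. Marker effects default to a strong
#' log2 shift of 4 so the cohort is learnable end to end at this scale.
#'
#' @param seed integer seed.
#' @param n_samples approximate cohort size; default 500.
#' @param n_genes number of genes; default 5000.
#' @param effect_size marker log2 shift; default 4.
#' @param ... further overrides passed to [synth_spec()].
#' @return as [sim_expression()], plus `scheme` (the [ball_scheme()]).
#' @export
make_cohort_like <- function(seed = 1L, n_samples = 500L, n_genes = 5000L,
                             effect_size = 4, ...) {
  scheme <- ball_scheme()
  # head proportions as observed in large B-ALL cohorts; the tail tapers
  # over the remaining cohort share
  tail_p <- seq(8, 1, length.out = 17)
  tail_p <- tail_p / sum(tail_p) * (100 - 18.6 - 15.4 - 10.8)
  props <- c(18.6, 15.4, 10.8, tail_p)
  sizes <- round(props / 100 * n_samples)
  sizes <- pmax(sizes, 5L)
  # absorb the floor surplus proportionally in the classes above the floor
  surplus <- sum(sizes) - n_samples
  while (surplus != 0L) {
    big <- which(sizes > 5L)
    adj <- round(surplus * sizes[big] / sum(sizes[big]))
    if (all(adj == 0L)) adj[which.max(sizes[big])] <- sign(surplus)
    sizes[big] <- pmax(sizes[big] - adj, 5L)
    surplus <- sum(sizes) - n_samples
  }
  # name the three largest after the cohort's dominant subtypes
  nm <- c("Ph-like", "High hyperdiploid", "ETV6-RUNX1",
          setdiff(scheme$labels, c("Ph-like", "High hyperdiploid", "ETV6-RUNX1")))
  spec <- synth_spec(n_genes = n_genes, class_sizes = sizes,
                     markers_per_class = 20L, effect_size = effect_size,
                     class_names = nm, seed = seed, ...)
  out <- sim_expression(spec)
  out$scheme <- scheme
  out
}
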