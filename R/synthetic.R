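#' Synthetic two-group pilot with normally distributed features
#'
#' Generates an `m x 2n` matrix in which a fraction `p1` of features carry a
#' group-mean shift of `delta` (random sign) on Gaussian noise with standard
#' deviation `sigma`; the remaining features are null. The ground truth
#' (changed features and shift signs) is attached as attribute `truth`.
#'
#' @param m Number of features.
#' @param n Replicates per group.
#' @param p1 Fraction of changed features.
#' @param delta Absolute mean shift of changed features.
#' @param sigma Within-group standard deviation.
#' @param name Omic label.
#' @param cost Per-replicate cost.
#' @param seed Integer seed (reproducible: same arguments, same data).
#' @return An [omic_pilot()] with attribute `truth`.
#' @export
gen_normal_omic <- function(m, n, p1, delta, sigma, name = "normal_omic",
                            cost = 1, seed = 1L) {
  set.seed(seed)
  n_de <- round(p1 * m)
  de <- seq_len(n_de)
  signs <- sample(c(-1, 1), n_de, replace = TRUE)
  mat <- matrix(stats::rnorm(m * 2 * n, mean = 0, sd = sigma), nrow = m)
  if (n_de > 0)
    mat[de, (n + 1):(2 * n)] <- mat[de, (n + 1):(2 * n)] + signs * delta
  rownames(mat) <- sprintf("f%04d", seq_len(m))
  colnames(mat) <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  pilot <- omic_pilot(name, mat, rep(c("A", "B"), each = n),
                      data_type = "normal", p1 = max(p1, 1e-3), cost = cost)
  attr(pilot, "truth") <- list(de = rownames(mat)[de], signs = signs,
                               delta = delta, sigma = sigma)
  pilot
}

#' Synthetic two-group pilot with negative-binomial counts
#'
#' Feature baseline means are log-normal around `mu`; counts are NB draws
#' honoring the mean-variance relation `var = mu + mu^2 * phi` (Poisson at
#' `phi = 0`), scaled per sample by the supplied sequencing-depth factors.
#' A fraction `p1` of features is changed by fold `omega` between the
#' groups, half up- and half down-regulated in B. Down-regulation in B is
#' implemented as elevation of the baseline in A, which keeps the expected
#' library sizes of the two groups equal: the generator is
#' composition-neutral, so the column-sum depth normalization is not
#' confounded by the injected signal.
#'
#' @inheritParams gen_normal_omic
#' @param mu Median baseline mean count.
#' @param phi NB dispersion.
#' @param omega Fold change of changed features.
#' @param depth Per-sample depth factors, length `2n` (default all 1).
#' @param sdlog Spread of baseline means on the log scale (default 0.7).
#' @return An [omic_pilot()] with attribute `truth`.
#' @export
gen_count_omic <- function(m, n, p1, mu = 30, phi = 0.4, omega = 2,
                           depth = rep(1, 2 * n), sdlog = 0.7,
                           name = "count_omic", cost = 1, seed = 1L) {
  stopifnot(length(depth) == 2 * n, all(depth > 0))
  set.seed(seed)
  n_de <- round(p1 * m)
  de <- seq_len(n_de)
  base <- stats::rlnorm(m, meanlog = log(mu), sdlog = sdlog)
  fold <- rep(1, m)                     # fold of B relative to A
  foldA <- rep(1, m); foldB <- rep(1, m)
  if (n_de > 0) {
    up <- stats::runif(n_de) < 0.5
    fold[de] <- ifelse(up, omega, 1 / omega)
    foldB[de[up]] <- omega              # up-regulated in B
    foldA[de[!up]] <- omega             # down in B = elevated baseline in A
  }
  mean_mat <- cbind(matrix(base * foldA, m, n), matrix(base * foldB, m, n))
  mean_mat <- sweep(mean_mat, 2L, depth, "*")
  draw <- function(mm) {
    if (phi <= 1e-12) stats::rpois(length(mm), mm)
    else stats::rnbinom(length(mm), size = 1 / phi, mu = mm)
  }
  mat <- matrix(draw(mean_mat), nrow = m)
  rownames(mat) <- sprintf("f%04d", seq_len(m))
  colnames(mat) <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  pilot <- omic_pilot(name, mat, rep(c("A", "B"), each = n),
                      data_type = "count", p1 = max(p1, 1e-3), cost = cost)
  attr(pilot, "truth") <- list(de = rownames(mat)[de], mu = mu, phi = phi,
                               omega = omega, fold = fold, depth = depth)
  pilot
}

#' Synthetic two-group pilot with binary features
#'
#' Null features share a per-feature probability drawn uniformly from
#' `[0.05, 0.95]` in both groups; changed features use `(pA, pB)`.
#'
#' @inheritParams gen_normal_omic
#' @param pA,pB Group proportions of changed features.
#' @return An [omic_pilot()] with attribute `truth`.
#' @export
gen_binary_omic <- function(m, n, p1, pA = 0.2, pB = 0.7,
                            name = "binary_omic", cost = 1, seed = 1L) {
  set.seed(seed)
  n_de <- round(p1 * m)
  de <- seq_len(n_de)
  p_null <- stats::runif(m, 0.05, 0.95)
  probA <- p_null; probB <- p_null
  if (n_de > 0) { probA[de] <- pA; probB[de] <- pB }
  mat <- cbind(matrix(stats::rbinom(m * n, 1, rep(probA, n)), m),
               matrix(stats::rbinom(m * n, 1, rep(probB, n)), m))
  rownames(mat) <- sprintf("f%04d", seq_len(m))
  colnames(mat) <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  pilot <- omic_pilot(name, mat, rep(c("A", "B"), each = n),
                      data_type = "binary", p1 = max(p1, 1e-3), cost = cost)
  attr(pilot, "truth") <- list(de = rownames(mat)[de], pA = pA, pB = pB)
  pilot
}

#' Default six-omic synthetic pilot study
#'
#' A compact multi-omic pilot mimicking the shape of a typical
#' transcriptome/epigenome/proteome/metabolome study: six omics whose
#' feature counts are one tenth of a published multi-omic pilot (so the
#' full estimation-plus-design pipeline runs in seconds), with two
#' sequencing omics kept as raw counts and the remaining platforms as
#' normally distributed (log-scale) data.
#'
#' @param n Replicates per group (default 10).
#' @param seed Integer seed; per-omic seeds are derived from it.
#' @return Named list of [omic_pilot()] objects.
#' @export
gen_multiomic_pilot <- function(n = 10, seed = 1L) {
  specs <- list(
    list(name = "RNA-seq", m = 1276, p1 = 0.4, type = "count",
         mu = 30, phi = 0.3, omega = 2.5),
    list(name = "miRNA-seq", m = 47, p1 = 0.2, type = "count",
         mu = 50, phi = 0.4, omega = 2),
    list(name = "ChIP-seq", m = 2388, p1 = 0.2, type = "normal",
         delta = 1.35, sigma = 0.96),
    list(name = "DNase-seq", m = 5279, p1 = 0.2, type = "normal",
         delta = 0.51, sigma = 0.49),
    list(name = "Metabolomics", m = 6, p1 = 0.6, type = "normal",
         delta = 1.20, sigma = 0.52),
    list(name = "Proteomics", m = 108, p1 = 0.2, type = "normal",
         delta = 1.16, sigma = 1.05))
  out <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    sd_i <- as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
    if (s$type == "count") {
      set.seed(sd_i + 1L)
      dep <- exp(stats::rnorm(2 * n, 0, 0.2))
      gen_count_omic(s$m, n, s$p1, mu = s$mu, phi = s$phi, omega = s$omega,
                     depth = dep, name = s$name, seed = sd_i)
    } else
      gen_normal_omic(s$m, n, s$p1, delta = s$delta, sigma = s$sigma,
                      name = s$name, seed = sd_i)
  })
  names(out) <- vapply(specs, `[[`, character(1), "name")
  out
}

#' Synthetic multi-omic classification dataset
#'
#' Builds `omics` blocks of Gaussian variables for a `classes`-class
#' problem. In each block, `informative` variables carry class-dependent
#' means separated by `separation` (in noise-SD units); the rest are pure
#' noise. By default each block carries its own, orthogonal informative
#' variables (complementary information: each block separates the classes
#' along independent directions); with `redundant = TRUE` every block
#' repeats the signal pattern of the first (adding blocks then adds no new
#' information).
#'
#' @param n_per_class Observations per class.
#' @param classes Number of classes (default 2).
#' @param omics Number of omic blocks.
#' @param p Variables per block.
#' @param informative Informative variables per block.
#' @param separation Class-mean separation in SD units.
#' @param redundant Make all blocks carry the same signal?
#' @param seed Integer seed.
#' @return A [multiomic_ml_data()] object with attribute `truth` (the
#'   informative variable names per block).
#' @export
gen_ml_dataset <- function(n_per_class = 30, classes = 2, omics = 2, p = 50,
                           informative = 5, separation = 1,
                           redundant = FALSE, seed = 1L) {
  set.seed(seed)
  N <- n_per_class * classes
  ids <- sprintf("S%03d", seq_len(N))
  Y <- factor(rep(paste0("class", seq_len(classes)), each = n_per_class))
  names(Y) <- ids
  # class-mean patterns: orthogonal-ish random directions per block
  blocks <- vector("list", omics)
  truth <- vector("list", omics)
  sig_pattern <- NULL
  for (o in seq_len(omics)) {
    mat <- matrix(stats::rnorm(N * p), N, p)
    if (redundant && o > 1L) {
      pattern <- sig_pattern
    } else {
      # every informative variable carries class means with SD exactly
      # `separation` (random class ordering), so each one is truly signal
      pattern <- vapply(seq_len(max(informative, 1L)), function(j) {
        v <- sample(seq_len(classes))
        (v - mean(v)) / stats::sd(v) * separation
      }, numeric(classes))
      pattern <- matrix(pattern, classes, max(informative, 1L))
      if (o == 1L) sig_pattern <- pattern
    }
    for (cl in seq_len(classes)) {
      rows <- which(as.integer(Y) == cl)
      mat[rows, seq_len(informative)] <-
        mat[rows, seq_len(informative)] +
        matrix(pattern[cl, ], length(rows), informative, byrow = TRUE)
    }
    rownames(mat) <- ids
    colnames(mat) <- sprintf("v%03d", seq_len(p))
    blocks[[o]] <- mat
    truth[[o]] <- colnames(mat)[seq_len(informative)]
  }
  names(blocks) <- paste0("omic", seq_len(omics))
  names(truth) <- names(blocks)
  out <- multiomic_ml_data(blocks, Y)
  attr(out, "truth") <- truth
  out
}

#' Write a synthetic multi-omic pilot to disk
#'
#' Materializes matrices (TSV), group labels (TSV) and the ground-truth
#' tables (TSV) plus a YAML echo of the generating parameters, for use
#' outside R.
#'
#' @param pilots Named list of [omic_pilot()] objects (e.g. from
#'   [gen_multiomic_pilot()]).
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_synthetic_pilot <- function(pilots, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- list()
  for (p in pilots) {
    slug <- gsub("[^A-Za-z0-9]+", "_", p$name)
    utils::write.table(data.frame(feature = rownames(p$matrix), p$matrix,
                                  check.names = FALSE),
                       file.path(dir, paste0(slug, "_matrix.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(p$matrix),
                                  group = p$groups),
                       file.path(dir, paste0(slug, "_groups.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- attr(p, "truth")
    if (!is.null(tr))
      utils::write.table(data.frame(feature = tr$de),
                         file.path(dir, paste0(slug, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    spec[[p$name]] <- list(data_type = p$data_type, m = nrow(p$matrix),
                           n_per_group = as.integer(table(p$groups)),
                           p1 = p$p1, cost = p$cost)
  }
  yaml::write_yaml(spec, file.path(dir, "pilot_spec.yaml"))
  invisible(dir)
}
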