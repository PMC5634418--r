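#' Specification for a synthetic two-group expression dataset
#'
#' Describes a planted-structure generator emulating two-class microarray /
#' expression studies: thousands of continuous features, tens of samples per
#' class, a minority of class-informative features whose between-class mean
#' shift (in noise-SD units) controls separability, and optional redundant
#' blocks of correlated informative features that plant solution multiplicity
#' by construction.
#'
#' @param n_features total number of features (rows).
#' @param n_samples_per_class integer pair `c(n_positive, n_negative)`.
#' @param n_informative number of features with a class-mean shift
#'   (`<= n_features`); they occupy the first rows.
#' @param effect_size between-class mean shift of informative features in
#'   units of `noise_sd` (>= 0). Around 0.8 gives a "difficult" problem,
#'   2.5 an "easy" one.
#' @param n_redundant_blocks number of correlated blocks carved out of the
#'   informative features.
#' @param block_size features per block; `n_redundant_blocks * block_size`
#'   must not exceed `n_informative`.
#' @param within_block_correlation target pairwise correlation within a block,
#'   in `[0, 1)`; induced by a shared per-sample latent factor.
#' @param noise_sd standard deviation of the Gaussian noise (> 0).
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   dataset.
#' @return an object of class `SyntheticSpec`.
#' @seealso [generate_dataset()], [synthetic_preset()]
#' @export
synthetic_spec <- function(n_features = 1000L,
                           n_samples_per_class = c(30L, 30L),
                           n_informative = 10L,
                           effect_size = 1.5,
                           n_redundant_blocks = 0L,
                           block_size = 3L,
                           within_block_correlation = 0.8,
                           noise_sd = 1,
                           seed = 1L) {
  fail_if(!is_count(n_features), "n_features must be a positive integer")
  fail_if(length(n_samples_per_class) != 2L ||
            !all(vapply(n_samples_per_class, is_count, TRUE)),
          "n_samples_per_class must be two positive integers")
  fail_if(!is_count(n_informative, min = 0L) || n_informative > n_features,
          "n_informative must be in 0..n_features")
  fail_if(!is_number(effect_size) || effect_size < 0,
          "effect_size must be a real >= 0")
  fail_if(!is_count(n_redundant_blocks, min = 0L),
          "n_redundant_blocks must be a non-negative integer")
  fail_if(!is_count(block_size), "block_size must be a positive integer")
  fail_if(n_redundant_blocks * block_size > n_informative,
          "n_redundant_blocks * block_size (%d) exceeds n_informative (%d)",
          n_redundant_blocks * block_size, n_informative)
  fail_if(!is_number(within_block_correlation) ||
            within_block_correlation < 0 || within_block_correlation >= 1,
          "within_block_correlation must be in [0, 1)")
  fail_if(!is_number(noise_sd) || noise_sd <= 0, "noise_sd must be > 0")
  structure(
    list(n_features = as.integer(n_features),
         n_samples_per_class = as.integer(n_samples_per_class),
         n_informative = as.integer(n_informative),
         effect_size = effect_size,
         n_redundant_blocks = as.integer(n_redundant_blocks),
         block_size = as.integer(block_size),
         within_block_correlation = within_block_correlation,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

#' Built-in generator presets mirroring easy and difficult study regimes
#'
#' `"easy"`: strong, partly redundant signal (effect 2.5, three correlated
#' blocks of three informative features, 30+30 samples, 1000 features) —
#' near-ceiling classification and multiplicity by construction.
#' `"difficult"`: weak signal and few samples (effect 0.8, 15+15 samples,
#' 2000 features, no redundant blocks).
#'
#' @param preset `"easy"` or `"difficult"`.
#' @param seed integer seed for the generator.
#' @return a [synthetic_spec()] object.
#' @export
synthetic_preset <- function(preset = c("easy", "difficult"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    easy = synthetic_spec(
      n_features = 1000L, n_samples_per_class = c(30L, 30L),
      n_informative = 12L, effect_size = 2.5,
      n_redundant_blocks = 3L, block_size = 3L,
      within_block_correlation = 0.8, noise_sd = 1, seed = seed
    ),
    difficult = synthetic_spec(
      n_features = 2000L, n_samples_per_class = c(15L, 15L),
      n_informative = 10L, effect_size = 0.8,
      n_redundant_blocks = 0L, block_size = 1L,
      within_block_correlation = 0, noise_sd = 1, seed = seed
    )
  )
}

#' Generate a synthetic two-group expression dataset
#'
#' Uninformative features are i.i.d. `N(0, noise_sd^2)` in both classes.
#' Informative features additionally receive a `+effect_size * noise_sd` mean
#' shift in the positive class ("case"). Features inside a redundant block
#' share a per-sample latent factor `z`:
#' `x = sqrt(rho) * z + sqrt(1 - rho) * eps`, scaled by `noise_sd`, giving
#' pairwise within-block correlation close to `rho`. Sample labels are
#' `"case"` (positive, first `n_samples_per_class[1]` columns) and
#' `"control"`.
#'
#' @param spec a [synthetic_spec()].
#' @return an [ExpressionDataset][expression_dataset]; feature ids are
#'   `f0001...`, with informative features first (block members first among
#'   them), sample ids `case_01.../control_01...`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_features = 50, seed = 7))
#' ds
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  m <- spec$n_features
  n_pos <- spec$n_samples_per_class[1L]
  n_neg <- spec$n_samples_per_class[2L]
  n <- n_pos + n_neg
  rho <- spec$within_block_correlation
  n_block <- spec$n_redundant_blocks * spec$block_size

  values <- with_seed(spec$seed, {
    x <- matrix(stats::rnorm(m * n, sd = spec$noise_sd), nrow = m, ncol = n)
    if (n_block > 0L) {
      for (b in seq_len(spec$n_redundant_blocks)) {
        rows <- ((b - 1L) * spec$block_size + 1L):(b * spec$block_size)
        z <- stats::rnorm(n)                       # shared latent, one per sample
        eps <- matrix(stats::rnorm(spec$block_size * n), nrow = spec$block_size)
        x[rows, ] <- spec$noise_sd *
          (sqrt(rho) * matrix(z, nrow = spec$block_size, ncol = n, byrow = TRUE) +
             sqrt(1 - rho) * eps)
      }
    }
    if (spec$n_informative > 0L) {
      x[seq_len(spec$n_informative), seq_len(n_pos)] <-
        x[seq_len(spec$n_informative), seq_len(n_pos)] +
        spec$effect_size * spec$noise_sd
    }
    x
  })
  width <- max(4L, nchar(as.character(m)))
  rownames(values) <- sprintf(paste0("f%0", width, "d"), seq_len(m))
  colnames(values) <- c(sprintf("case_%02d", seq_len(n_pos)),
                        sprintf("control_%02d", seq_len(n_neg)))
  labels <- stats::setNames(rep(c("case", "control"), c(n_pos, n_neg)),
                            colnames(values))
  expression_dataset(values, labels, positive_class = "case")
}

#' Ids of the planted informative features of a spec
#' @param spec a [synthetic_spec()].
#' @return character vector (possibly empty).
#' @export
informative_features <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  width <- max(4L, nchar(as.character(spec$n_features)))
  sprintf(paste0("f%0", width, "d"), seq_len(spec$n_informative))
}
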