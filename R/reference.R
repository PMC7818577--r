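#' Synthetic gene-expression-like training data
#'
#' Generates a bounded, high-dimensional binary-classification table of the
#' shape the secure trainer targets: hundreds of samples, up to
#' \eqn{10^4}-scale numeric features, values well inside the fixed-point
#' window. Features are drawn from a normal distribution truncated to
#' `feature_scale` (clamped at \eqn{\pm}`feature_scale`); a sparse
#' ground-truth weight vector scores each sample, and labels are either the
#' sign of the score (with an enforced margin, giving a linearly separable
#' set) or Bernoulli draws from the sigmoid of the score, with an optional
#' label-flip noise rate on top.
#'
#' @param n_samples,n_features Table dimensions.
#' @param sparsity Fraction of features with nonzero true weight.
#' @param feature_scale Bound on feature magnitudes (must be \eqn{< 2^b}).
#' @param label_noise Probability of flipping each label.
#' @param separable If `TRUE`, labels are `score > 0` and samples with
#'   `|score| < margin` are redrawn; if `FALSE`, labels come from the sigmoid
#'   of the score.
#' @param margin Minimum |score| per sample in separable mode.
#' @param intercept True intercept added to every score (shifts class
#'   balance).
#' @param seed Seed; the table is a deterministic function of it.
#' @return A list of class `synth_lr`: `data` (tibble of `feature_*` columns
#'   plus `label`) and `true_weights` (tibble `term`, `weight`, bias first).
#' @examples
#' d <- synth_lr_data(n_samples = 50, n_features = 8, seed = 42)
#' table(d$data$label)
#' @export
synth_lr_data <- function(n_samples, n_features, sparsity = 0.2,
                          feature_scale = 1, label_noise = 0,
                          separable = TRUE, margin = 0.2, intercept = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples >= 1, n_features >= 1, feature_scale > 0)
  n_active <- max(1L, round(sparsity * n_features))
  w_true <- numeric(n_features)
  active <- sample.int(n_features, n_active)
  w_true[active] <- stats::rnorm(n_active)
  w_true <- w_true / sqrt(sum(w_true^2))

  draw <- function(n) {
    X <- matrix(stats::rnorm(n * n_features, sd = feature_scale / 2), n, n_features)
    pmin(pmax(X, -feature_scale), feature_scale)
  }
  X <- draw(n_samples)
  score <- as.numeric(X %*% w_true) + intercept
  if (separable) {
    tries <- 0L
    while (any(abs(score) < margin) && tries < 200L) {
      bad <- which(abs(score) < margin)
      X[bad, ] <- draw(length(bad))
      score <- as.numeric(X %*% w_true) + intercept
      tries <- tries + 1L
    }
    if (any(abs(score) < margin))
      stop("could not achieve the requested margin; lower `margin` or `sparsity`")
    t <- as.numeric(score > 0)
  } else {
    t <- stats::rbinom(n_samples, 1, stats::plogis(4 * score))
  }
  if (label_noise > 0) {
    flip <- stats::runif(n_samples) < label_noise
    t[flip] <- 1 - t[flip]
  }
  tbl <- tibble::as_tibble(X, .name_repair = ~ paste0("feature_", seq_len(n_features)))
  tbl$label <- t
  structure(list(
    data = tbl,
    true_weights = tibble::tibble(term = c("bias", paste0("feature_", seq_len(n_features))),
                                  weight = c(intercept, w_true))
  ), class = "synth_lr")
}

#' @export
print.synth_lr <- function(x, ...) {
  cat(sprintf("<synth_lr> %d samples x %d features, %d positive\n",
              nrow(x$data), ncol(x$data) - 1L, sum(x$data$label)))
  invisible(x)
}

#' In-the-clear float reference trainer
#'
#' The plaintext analogue of the secure protocol in double precision:
#' full-batch gradient descent on the clipped-ReLU model,
#' \eqn{w \leftarrow w + \eta \, X^\top (t - \rho(X w))}, zero-initialized,
#' for exactly `iterations` steps.
#'
#' @inheritParams train_lr_secure
#' @return An object of class `clear_lr_fit` with a `weights` tibble.
#' @export
train_lr_clear <- function(data, learning_rate, iterations) {
  xt <- lr_design(data)
  w <- numeric(ncol(xt$X))
  it <- 0L
  while (it < iterations) {
    o <- rho_clear(as.numeric(xt$X %*% w))
    w <- w + learning_rate * as.numeric(t(xt$X) %*% (xt$t - o))
    it <- it + 1L
  }
  structure(list(weights = tibble::tibble(term = xt$terms, estimate = w),
                 learning_rate = learning_rate, iterations = iterations,
                 n = nrow(xt$X), m = ncol(xt$X) - 1L),
            class = "clear_lr_fit")
}

#' @export
print.clear_lr_fit <- function(x, ...) {
  cat(sprintf("<clear_lr_fit> %d samples x %d features, %d iterations (eta = %g)\n",
              x$n, x$m, x$iterations, x$learning_rate))
  print(x$weights, n = 6)
  invisible(x)
}

#' Fixed-point in-the-clear reference trainer
#'
#' A single-machine simulation of the exact ring pipeline the secure protocol
#' executes: fixed-point encoding, modular matrix products, the exact
#' activation algebra \eqn{P (z' + G (2^a - z'))} with plaintext 0/1 flags,
#' and the share-split truncation rule applied at the same three points per
#' iteration. This is the oracle for secure/clear equivalence.
#'
#' The `trunc_model` controls the truncation randomness:
#' \describe{
#'   \item{`"signed"`}{exact two's-complement \eqn{\lfloor x / 2^d \rfloor}
#'     (no share split, no error) — the idealized pipeline;}
#'   \item{`"split"`}{each truncation draws a fresh uniform Alice share and
#'     applies both parties' local rules (the weak oracle, faithful error
#'     model);}
#'   \item{a list of recorded Alice-share vectors}{replays the exact splits
#'     observed in a secure run (`record_truncations = TRUE`), reproducing
#'     its weights bit for bit — the strong oracle.}
#' }
#'
#' @inheritParams train_lr_secure
#' @param trunc_model `"signed"`, `"split"`, or a recorded split list.
#' @return An object of class `fixed_lr_fit` with decoded `weights` and the
#'   raw ring weights.
#' @export
train_lr_fixed <- function(data, learning_rate, iterations, fmt = fp_format(),
                           trunc_model = "split", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xt <- lr_design(data)
  lam <- fmt$lam; a <- fmt$a
  X <- fp_encode(xt$X, fmt)
  Xt <- t(X)
  tenc <- fp_encode(xt$t, fmt)
  n <- nrow(X); m1 <- ncol(X)
  w <- matrix(rs_from_signed(numeric(m1), lam), m1, 1)
  eta_enc <- fp_encode(learning_rate, fmt)
  replay <- is.list(trunc_model)
  event <- 0L
  trunc_plain <- function(v, d) {
    if (identical(trunc_model, "signed")) {
      return(rs_from_signed(floor(rs_to_signed(as.numeric(v), lam) / 2^d), lam))
    }
    va <- if (replay) {
      event <<- event + 1L
      if (event > length(trunc_model)) stop("recorded truncation trace exhausted")
      trunc_model[[event]]
    } else rs_rand(length(v), lam)
    vb <- rs_sub(as.numeric(v), va, lam)
    rs_add(rs_trunc(va, d, lam, 0L), rs_trunc(vb, d, lam, 1L), lam)
  }
  it <- 0L
  while (it < iterations) {
    s <- trunc_plain(rs_matmul(X, w, lam), a)
    o <- rho_fixed_plain(s, fmt)
    e <- rs_sub(as.numeric(tenc), o, lam); dim(e) <- c(n, 1)
    g <- trunc_plain(rs_matmul(Xt, e, lam), a)
    upd <- trunc_plain(rs_mul(as.numeric(g), eta_enc, lam), a)
    w <- matrix(rs_add(as.numeric(w), upd, lam), m1, 1)
    it <- it + 1L
  }
  weights <- fp_decode(as.numeric(w), fmt)
  structure(list(weights = tibble::tibble(term = xt$terms, estimate = weights),
                 ring_weights = as.numeric(w), fmt = fmt,
                 learning_rate = learning_rate, iterations = iterations,
                 trunc_model = if (replay) "replay" else trunc_model,
                 n = n, m = m1 - 1L),
            class = "fixed_lr_fit")
}

#' @export
print.fixed_lr_fit <- function(x, ...) {
  cat(sprintf("<fixed_lr_fit> %d samples x %d features, %d iterations (trunc_model = %s)\n",
              x$n, x$m, x$iterations, x$trunc_model))
  print(x$weights, n = 6)
  invisible(x)
}

# plaintext fixed-point clipped ReLU on ring values, replicating the secure
# protocol's algebra exactly (no truncation; P, G read off the bit pattern)
rho_fixed_plain <- function(s, fmt) {
  lam <- fmt$lam; a <- fmt$a; b <- fmt$b
  k <- a + b + 1L
  zp <- rs_add(as.numeric(s), rs_from_signed(2^(a - 1), lam), lam)
  bits <- rs_bits(zp, k, lam)
  pos <- 1 - bits[, k]
  geq1 <- as.numeric(rowSums(bits[, (a + 1):(a + b), drop = FALSE]) > 0)
  one <- rs_from_signed(2^a, lam)
  u <- rs_add(zp, rs_mul(rs_from_signed(geq1, lam), rs_sub(one, zp, lam), lam), lam)
  rs_mul(rs_from_signed(pos, lam), u, lam)
}

#' Classify with clipped-ReLU model weights
#'
#' Scores `data` with the weights of any of the three trainers and thresholds
#' the activation at 1/2 (equivalently, the linear score at 0).
#'
#' @param object A `secure_lr_fit`, `clear_lr_fit` or `fixed_lr_fit`.
#' @param newdata A data frame of features (a `label` column is ignored).
#' @param ... Unused.
#' @return A tibble with `prob` (clipped-ReLU output) and `pred` (0/1).
#' @export
predict.clear_lr_fit <- function(object, newdata, ...) {
  w <- object$weights$estimate
  feats <- newdata[setdiff(names(newdata), "label")]
  X <- cbind(1, as.matrix(feats))
  prob <- rho_clear(as.numeric(X %*% w))
  tibble::tibble(prob = prob, pred = as.numeric(prob >= 0.5))
}

#' @rdname predict.clear_lr_fit
#' @export
predict.secure_lr_fit <- predict.clear_lr_fit

#' @rdname predict.clear_lr_fit
#' @export
predict.fixed_lr_fit <- predict.clear_lr_fit

#' Held-out classification accuracy
#'
#' @param fit A fitted model from any of the trainers.
#' @param data A data frame with features and a `label` column.
#' @return Accuracy in \eqn{[0, 1]}.
#' @export
accuracy <- function(fit, data) {
  mean(predict(fit, data)$pred == data$label)
}

#' Seeded k-fold cross-validation accuracy
#'
#' Assigns samples to `k` folds with a seeded shuffle, trains on each
#' training split with the supplied trainer and averages held-out accuracy.
#'
#' @param data Features + `label` table.
#' @param trainer A function `function(train_data) -> fit`.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return Mean held-out accuracy across folds.
#' @export
cv_accuracy <- function(data, trainer, k = 5, seed = 1) {
  n <- nrow(data)
  folds <- with_preserved_seed(seed, sample(rep_len(seq_len(k), n)))
  accs <- vapply(seq_len(k), function(f) {
    fit <- trainer(data[folds != f, , drop = FALSE])
    accuracy(fit, data[folds == f, , drop = FALSE])
  }, numeric(1))
  mean(accs)
}
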