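#' Secure logistic-regression training on secret shares
#'
#' Runs the full-gradient-descent training protocol on a data frame whose
#' feature columns are numeric and whose `label` column is 0/1. The table is
#' encoded into fixed point (a bias column of ones is prepended), secret
#' shared between the two simulated data processors, and trained for exactly
#' `iterations` rounds of: one secure inner-product batch
#' \eqn{s = X w} followed by a deferred truncation; one batched secure
#' clipped-ReLU activation \eqn{o = \rho(s)}; the local error \eqn{e = t - o};
#' one secure gradient product \eqn{X^\top e} followed by truncation; and a
#' local learning-rate scaling \eqn{Q(\eta) \cdot g} with a final local
#' truncation. Weights start at the all-zeros sharing and the iteration count
#' is fixed in advance (no early stopping — a data-dependent stop would leak).
#'
#' The learning rate enters as the public constant \eqn{Q(\eta)}; the update
#' adds the plain sum of per-sample gradients (no division by the sample
#' count — fold any normalization into `learning_rate`).
#'
#' @param data A data frame: numeric feature columns plus a 0/1 `label`
#'   column.
#' @param learning_rate Public learning rate \eqn{\eta}.
#' @param iterations Public, fixed iteration count.
#' @param fmt An [fp_format()].
#' @param variant Bit-decomposition circuit, `"ripple"` or `"lookahead"`.
#' @param seed Seed for the trusted initializer's streams and the sharing
#'   masks.
#' @param record_truncations Keep the Alice-side share at every truncation
#'   event (enables the bit-exact fixed-point replay oracle).
#' @return An object of class `secure_lr_fit`: decoded weights, the shared
#'   weights, the session (with channel counters and consumption tallies),
#'   and the call parameters.
#' @examples
#' d <- synth_lr_data(n_samples = 32, n_features = 4, seed = 1)
#' fit <- train_lr_secure(d$data, learning_rate = 0.125, iterations = 5, seed = 1)
#' tidy(fit)
#' @export
train_lr_secure <- function(data, learning_rate, iterations,
                            fmt = fp_format(), variant = c("ripple", "lookahead"),
                            seed = NULL, record_truncations = FALSE) {
  variant <- match.arg(variant)
  xt <- lr_design(data)
  n <- nrow(xt$X); m1 <- ncol(xt$X)
  if (!is.null(seed)) set.seed(seed)
  plan <- randomness_plan(n, m1 - 1L, iterations, fmt, variant)
  rand <- ti_gen(plan, fmt)
  ctx <- mpc_session(fmt, rand, variant)
  if (record_truncations) start_trunc_recording(ctx)

  Xs <- share_secret(fp_encode(xt$X, fmt), fmt$lam)
  ts <- share_secret(fp_encode(xt$t, fmt), fmt$lam)
  w <- train_secure(Xs, ts, learning_rate, iterations, ctx)

  weights <- fp_decode(open_shares(w), fmt)
  structure(list(
    weights = tibble::tibble(term = xt$terms, estimate = as.numeric(weights)),
    shared_weights = w, session = ctx, fmt = fmt,
    learning_rate = learning_rate, iterations = iterations,
    variant = variant, n = n, m = m1 - 1L,
    trunc_splits = if (record_truncations) ctx$trunc_record$splits else NULL
  ), class = "secure_lr_fit")
}

#' @export
print.secure_lr_fit <- function(x, ...) {
  cat(sprintf("<secure_lr_fit> %d samples x %d features, %d iterations (eta = %g, %s decomposition)\n",
              x$n, x$m, x$iterations, x$learning_rate, x$variant))
  cat(sprintf("  channel: %d rounds, %.0f bytes per direction\n",
              x$session$rounds, x$session$bytes_a2b))
  print(x$weights, n = 6)
  invisible(x)
}

#' Protocol-level secure training on shared tensors
#'
#' The core loop of [train_lr_secure()], exposed for callers that already
#' hold shares (e.g. assembled from owners' share files): shared design
#' matrix in, shared weights out. The session must carry randomness sized by
#' [randomness_plan()] for the same dimensions.
#'
#' @param Xs Shared design matrix (`n x (m+1)`, bias column included,
#'   fixed-point encoded).
#' @param ts Shared label vector (`n`, values \eqn{t_d 2^a}).
#' @param learning_rate,iterations Public hyperparameters.
#' @param ctx An [mpc_session()] with randomness attached.
#' @return The shared weight vector (`(m+1) x 1`).
#' @export
train_secure <- function(Xs, ts, learning_rate, iterations, ctx) {
  fmt <- ctx$fmt; lam <- fmt$lam
  n <- nrow(Xs$alice); m1 <- ncol(Xs$alice)
  tcol <- st_new(matrix(as.numeric(ts$alice), n, 1), matrix(as.numeric(ts$bob), n, 1), lam)
  Xt <- st_new(t(Xs$alice), t(Xs$bob), lam)
  zero <- rs_from_signed(numeric(m1), lam)
  w <- st_new(matrix(zero, m1, 1), matrix(zero, m1, 1), lam)
  eta_enc <- fp_encode(learning_rate, fmt)
  it <- 0L
  while (it < iterations) {
    set_phase(ctx, "inner_product")
    s <- truncate_shares(secure_matmul(Xs, w, ctx), fmt$a, ctx)
    o <- rho_secure(s, ctx)
    e <- local_sub(tcol, st_new(matrix(o$alice, n, 1), matrix(o$bob, n, 1), lam))
    set_phase(ctx, "gradient")
    g <- truncate_shares(secure_matmul(Xt, e, ctx), fmt$a, ctx)
    upd <- truncate_shares(local_scale(g, eta_enc), fmt$a, ctx)
    w <- local_add(w, upd)
    it <- it + 1L
  }
  w
}

# design matrix with bias column of ones, plus the 0/1 label vector
lr_design <- function(data) {
  if (!"label" %in% names(data)) stop("data must contain a `label` column")
  t <- as.numeric(data[["label"]])
  if (!all(t %in% c(0, 1))) stop("`label` must be 0/1")
  feats <- data[setdiff(names(data), "label")]
  if (!all(vapply(feats, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  X <- cbind(bias = 1, as.matrix(feats))
  list(X = X, t = matrix(t, ncol = 1), terms = colnames(X))
}

#' End-to-end multi-owner training
#'
#' Orchestrates the five deployment steps: (1) the trusted initializer emits
#' the correlated randomness; (2) each data owner encodes its values with the
#' fixed-point map and splits every value into two shares; (3) the data
#' processors assemble the shared design matrix and labels; (4) they run the
#' secure training protocol; (5) both send their weight shares to every
#' owner, who opens them. Sharing is per-value, so the result is identical
#' whether the table is split horizontally (by records), vertically (by
#' features) or arbitrarily (by cells): the sharing masks are drawn in
#' canonical cell order, independent of ownership.
#'
#' @param data The full training table (numeric features + 0/1 `label`).
#' @param n_owners Number of data owners the table is split across.
#' @param partition `"horizontal"`, `"vertical"` or `"arbitrary"`.
#' @inheritParams train_lr_secure
#' @return A `secure_lr_fit`, with the owner shard assignment attached as
#'   attribute `shards`.
#' @export
run_end_to_end <- function(data, n_owners = 2, partition = c("horizontal", "vertical", "arbitrary"),
                           learning_rate = 0.001, iterations = 10,
                           fmt = fp_format(), variant = c("ripple", "lookahead"),
                           seed = 1) {
  partition <- match.arg(partition)
  variant <- match.arg(variant)
  shards <- shard_table(data, n_owners, partition, seed = seed)
  # the processors see only the owners' cells; reassemble the table from the
  # shards (erroring if they are not a consistent partition) and share every
  # cell in canonical order, so ownership never influences the masks
  cells <- dplyr::bind_rows(shards)
  n <- max(cells$row); m <- max(cells$col)
  if (nrow(cells) != n * (m + 1) || anyDuplicated(cells[c("row", "col")]) > 0)
    stop("owner shards do not form a consistent partition of the table")
  feats <- matrix(NA_real_, n, m)
  labels <- numeric(n)
  is_label <- cells$col == 0
  labels[cells$row[is_label]] <- cells$value[is_label]
  feats[cbind(cells$row[!is_label], cells$col[!is_label])] <- cells$value[!is_label]
  if (anyNA(feats)) stop("owner shards have inconsistent dimensions")
  tbl <- tibble::as_tibble(feats, .name_repair = ~ paste0("feature_", seq_len(m)))
  tbl$label <- labels
  fit <- train_lr_secure(tbl, learning_rate, iterations, fmt, variant, seed = seed)
  attr(fit, "shards") <- shards
  fit
}

#' Split a training table across data owners
#'
#' Produces the per-owner cell lists for the three partition modes. Cells are
#' indexed over the design matrix (including the label column, index 0 for
#' the bias being excluded since it is public).
#'
#' @inheritParams run_end_to_end
#' @return A list of tibbles (`row`, `col`, `value`), one per owner; `col` is
#'   the feature index with 0 denoting the label.
#' @export
shard_table <- function(data, n_owners, partition = c("horizontal", "vertical", "arbitrary"),
                        seed = 1) {
  partition <- match.arg(partition)
  xt <- lr_design(data)
  feats <- xt$X[, -1, drop = FALSE]
  n <- nrow(feats); m <- ncol(feats)
  grid <- tibble::tibble(row = rep(seq_len(n), times = m + 1),
                         col = rep(0:m, each = n))
  grid$value <- ifelse(grid$col == 0, xt$t[grid$row, 1],
                       feats[cbind(grid$row, pmax(grid$col, 1))])
  owner <- switch(partition,
    horizontal = ((grid$row - 1) %% n_owners) + 1,
    vertical = (grid$col %% n_owners) + 1,
    arbitrary = with_preserved_seed(seed, sample.int(n_owners, nrow(grid), replace = TRUE)))
  lapply(seq_len(n_owners), function(i) grid[owner == i, , drop = FALSE])
}
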