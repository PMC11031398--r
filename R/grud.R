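# Decay-based recurrent diagnosis classifier. A gated recurrent unit over the
# yearly observation steps of a donor trajectory, extended with two
# decay mechanisms driven by the gap (in years) between consecutive steps:
# unobserved inputs decay from their last observed value toward an empirical
# mean, and the hidden state decays toward zero. Static covariates enter at
# the output layer. Implemented in base R with analytic backpropagation
# through time and Adam updates.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build per-donor observation sequences
#'
#' One step per calendar year with at least one observation; the input vector
#' is the binary attribute presence for that year, the mask marks which
#' attributes were observed (clinical text asserts presence only, so mask
#' equals input), and delta is the gap in years since the previous step.
#'
#' @param trajectory long observation data.frame.
#' @param donor_meta donor metadata (`donor_id`, `sex`, `death_age`).
#' @param attributes attribute universe (default: those present).
#' @return list with `sequences` (per donor: `x`, `m` T x d matrices and
#'   `delta`) and `static` (matrix: sex, scaled death age), both in
#'   `donor_meta` order.
#' @export
build_sequences <- function(trajectory, donor_meta, attributes = NULL) {
  obs <- trajectory[trajectory$present == 1 & !is.na(trajectory$year), ]
  attributes <- attributes %||% sort(unique(obs$attribute_id))
  seqs <- lapply(donor_meta$donor_id, function(d) {
    rows <- obs[obs$donor_id == d & obs$attribute_id %in% attributes, ]
    yrs <- sort(unique(rows$year))
    if (!length(yrs)) {
      x <- matrix(0, 1, length(attributes),
                  dimnames = list(NULL, attributes))
      return(list(x = x, m = x, delta = 1))
    }
    x <- matrix(0, length(yrs), length(attributes),
                dimnames = list(NULL, attributes))
    x[cbind(match(rows$year, yrs), match(rows$attribute_id, attributes))] <- 1
    list(x = x, m = x, delta = c(1, diff(yrs)))
  })
  static <- cbind(sex_female = as.numeric(donor_meta$sex == "F"),
                  death_age = donor_meta$death_age / 100)
  list(sequences = seqs, static = static, attributes = attributes)
}

grud_init <- function(d, h, c, s, seed = 1) {
  with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.1), nr, nc)
    list(Wz = rn(h, 2 * d + h), bz = numeric(h),
         Wr = rn(h, 2 * d + h), br = numeric(h),
         Wc = rn(h, 2 * d + h), bc = numeric(h),
         wgx = numeric(d) + 0.1, bgx = numeric(d),
         wgh = numeric(h) + 0.1, bgh = numeric(h),
         Wo = rn(c, h + s), bo = numeric(c))
  })
}

# forward pass over one sequence; returns class scores and, when cache=TRUE,
# all intermediates needed by the backward pass
grud_forward <- function(par, sq, static, xmean, cache = FALSE) {
  d <- ncol(sq$x); h <- length(par$bz); T_ <- nrow(sq$x)
  hs <- matrix(0, T_ + 1, h); xl <- xmean
  cc <- if (cache) vector("list", T_)
  hprev <- numeric(h)
  for (t in seq_len(T_)) {
    x <- sq$x[t, ]; m <- sq$m[t, ]; delta <- sq$delta[t]
    ax <- par$wgx * delta + par$bgx
    gx <- exp(-pmax(ax, 0))
    xh <- m * x + (1 - m) * (gx * xl + (1 - gx) * xmean)
    xl_new <- m * x + (1 - m) * xl
    ah <- par$wgh * delta + par$bgh
    gh <- exp(-pmax(ah, 0))
    hd <- gh * hprev
    u <- c(xh, m, hd)
    z <- sigmoid(drop(par$Wz %*% u) + par$bz)
    r <- sigmoid(drop(par$Wr %*% u) + par$br)
    uc <- c(xh, m, r * hd)
    ct <- tanh(drop(par$Wc %*% uc) + par$bc)
    hnew <- (1 - z) * hd + z * ct
    if (cache) {
      cc[[t]] <- list(x = x, m = m, delta = delta, ax = ax, gx = gx, xh = xh,
                      xl_prev = xl, ah = ah, gh = gh, hd = hd, u = u, z = z,
                      r = r, uc = uc, ct = ct, hprev = hprev)
    }
    xl <- xl_new; hprev <- hnew
  }
  feat <- c(hprev, static)
  o <- drop(par$Wo %*% feat) + par$bo
  p <- exp(o - max(o)); p <- p / sum(p)
  out <- list(p = p, feat = feat)
  if (cache) out$cache <- cc
  out
}

# analytic gradients of the cross-entropy loss for one sequence
grud_backward <- function(par, fw, sq, static, xmean, y_idx) {
  d <- ncol(sq$x); h <- length(par$bz); T_ <- nrow(sq$x)
  g <- lapply(par, function(p) p * 0)
  dy <- fw$p; dy[y_idx] <- dy[y_idx] - 1
  g$Wo <- dy %o% fw$feat
  g$bo <- dy
  dh <- drop(t(par$Wo[, seq_len(h), drop = FALSE]) %*% dy)
  dxl <- numeric(d)
  ix <- seq_len(d); im <- d + ix; ih <- 2 * d + seq_len(h)
  for (t in rev(seq_len(T_))) {
    s <- fw$cache[[t]]
    dz_pre <- dh * (s$ct - s$hd) * s$z * (1 - s$z)
    dct_pre <- dh * s$z * (1 - s$ct^2)
    g$Wz <- g$Wz + dz_pre %o% s$u;  g$bz <- g$bz + dz_pre
    g$Wc <- g$Wc + dct_pre %o% s$uc; g$bc <- g$bc + dct_pre
    drhd <- drop(t(par$Wc[, ih, drop = FALSE]) %*% dct_pre)
    dr_pre <- drhd * s$hd * s$r * (1 - s$r)
    g$Wr <- g$Wr + dr_pre %o% s$u;  g$br <- g$br + dr_pre
    dhd <- dh * (1 - s$z) + drhd * s$r +
      drop(t(par$Wz[, ih, drop = FALSE]) %*% dz_pre) +
      drop(t(par$Wr[, ih, drop = FALSE]) %*% dr_pre)
    dgh <- dhd * s$hprev
    dah <- -s$gh * dgh * (s$ah > 0)
    g$wgh <- g$wgh + dah * s$delta; g$bgh <- g$bgh + dah
    dxh <- drop(t(par$Wz[, ix, drop = FALSE]) %*% dz_pre) +
      drop(t(par$Wr[, ix, drop = FALSE]) %*% dr_pre) +
      drop(t(par$Wc[, ix, drop = FALSE]) %*% dct_pre)
    miss <- 1 - s$m
    dgx <- dxh * miss * (s$xl_prev - xmean)
    dax <- -s$gx * dgx * (s$ax > 0)
    g$wgx <- g$wgx + dax * s$delta; g$bgx <- g$bgx + dax
    # xl_{t-1} receives gradient from xh_t and from the xl recursion
    dxl <- dxh * miss * s$gx + dxl * miss
    dh <- dhd * s$gh
  }
  g
}

grud_loss_grad <- function(par, sq, static, xmean, y_idx) {
  fw <- grud_forward(par, sq, static, xmean, cache = TRUE)
  list(loss = -log(fw$p[y_idx] + 1e-12),
       grad = grud_backward(par, fw, sq, static, xmean, y_idx))
}

#' Fit the decay-based recurrent diagnosis classifier
#'
#' @param sequences list of per-donor sequences from [build_sequences()].
#' @param classes character vector of diagnosis labels.
#' @param static static covariate matrix (same row order), or NULL.
#' @param hidden hidden-state size (default 8).
#' @param epochs training epochs (default 50).
#' @param lr Adam learning rate.
#' @param l2 weight decay on the gate matrices.
#' @param seed integer seed (initialization and shuffling).
#' @return a `grud_model`.
#' @export
grud_fit <- function(sequences, classes, static = NULL, hidden = 8,
                     epochs = 50, lr = 0.01, l2 = 1e-4, seed = 1) {
  n <- length(sequences)
  stopifnot(n == length(classes))
  if (is.null(static)) static <- matrix(0, n, 0)
  levels <- sort(unique(classes))
  y <- match(classes, levels)
  d <- ncol(sequences[[1]]$x)
  # empirical presence rate per attribute across all steps
  xs <- do.call(rbind, lapply(sequences, function(s) s$x))
  xmean <- colMeans(xs)
  par <- grud_init(d, hidden, length(levels), ncol(static), seed)
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  losses <- numeric(epochs)
  with_seed(seed + 1, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (i in ord) {
        lg <- grud_loss_grad(par, sequences[[i]], static[i, ], xmean, y[i])
        tot <- tot + lg$loss
        step <- step + 1
        for (nm in names(par)) {
          gr <- lg$grad[[nm]]
          if (nm %in% c("Wz", "Wr", "Wc", "Wo")) gr <- gr + l2 * par[[nm]]
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[ep] <- tot / n
    }
  })
  structure(list(par = par, levels = levels, xmean = xmean,
                 losses = losses, hidden = hidden),
            class = "grud_model")
}

#' Predict diagnoses with a fitted recurrent classifier
#'
#' @param model a `grud_model`.
#' @param sequences list of sequences (attribute order must match training).
#' @param static static covariate matrix, or NULL.
#' @param type `"class"` (default) or `"prob"`.
#' @return character vector of predicted codes, or a probability matrix.
#' @export
grud_predict <- function(model, sequences, static = NULL,
                         type = c("class", "prob")) {
  type <- match.arg(type)
  n <- length(sequences)
  if (is.null(static)) static <- matrix(0, n, 0)
  probs <- t(vapply(seq_len(n), function(i)
    grud_forward(model$par, sequences[[i]], static[i, ], model$xmean)$p,
    numeric(length(model$levels))))
  colnames(probs) <- model$levels
  if (type == "prob") return(probs)
  model$levels[max.col(probs)]
}

#' @export
print.grud_model <- function(x, ...) {
  cat(sprintf("Decay-based recurrent classifier: %d classes, hidden size %d, final training loss %.4f\n",
              length(x$levels), x$hidden, x$losses[length(x$losses)]))
  invisible(x)
}
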