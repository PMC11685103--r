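# Five-branch CNN-GRU scorer for candidate MREs, one model per transcript
# region (3' UTR, CDS).
#
# Branch hyperparameters are fixed by the reference design: filter counts
# 35/50 (strides 2/3) for the extended-MRE branch, 16/32/62 (strides 2/3/4)
# for the chimera and duplex branches, 35/50 (strides 4/5) for the folding
# branch, 20/40/60 (strides 3/4/5) for conservation; max-pooling of width 2
# after each convolution, no padding; 24-unit GRUs with dropout 0.1; dense
# head 90/55/35 with leaky-ReLU, batch normalization and dropout 0.1; a
# single sigmoid output; Adam at learning rate 1e-4 with binary
# cross-entropy; up to 200 epochs with early stopping (patience 15).
#
# Kernel widths are not fixed by the reference design and default to
# per-layer values that keep every branch's conv/pool arithmetic valid
# (see the methods vignette). Max-pooling is skipped when the incoming
# length is below the pool width.

BRANCH_INPUTS <- list(
  mre = c(150L, 4L), chimera = c(53L, 4L), duplex = c(60L, 4L),
  fold = c(150L, 3L), conservation = c(150L, 1L)
)

#' Branch specification for the CNN-GRU scorer
#'
#' @param name one of `"mre"`, `"chimera"`, `"duplex"`, `"fold"`,
#'   `"conservation"`.
#' @param filters integer vector: number of filters per conv layer.
#' @param kernels integer vector: kernel width per conv layer.
#' @param strides integer vector: stride per conv layer.
#' @param pool_size max-pool width after each conv layer (default 2).
#' @param gru_units GRU hidden size (default 24).
#' @param dropout dropout rate (default 0.1).
#' @return a `branch_spec` list.
#' @export
branch_spec <- function(name, filters, kernels, strides, pool_size = 2L,
                        gru_units = 24L, dropout = 0.1) {
  name <- match.arg(name, names(BRANCH_INPUTS))
  stopifnot(length(filters) == length(kernels),
            length(filters) == length(strides))
  structure(list(name = name, filters = as.integer(filters),
                 kernels = as.integer(kernels), strides = as.integer(strides),
                 pool_size = as.integer(pool_size),
                 gru_units = as.integer(gru_units), dropout = dropout),
            class = "branch_spec")
}

#' Default branch specifications
#'
#' @return named list of the five default `branch_spec`s.
#' @export
default_branches <- function() {
  list(
    mre = branch_spec("mre", c(35L, 50L), c(9L, 9L), c(2L, 3L)),
    chimera = branch_spec("chimera", c(16L, 32L, 62L), c(6L, 3L, 2L), c(2L, 3L, 4L)),
    duplex = branch_spec("duplex", c(16L, 32L, 62L), c(6L, 3L, 2L), c(2L, 3L, 4L)),
    fold = branch_spec("fold", c(35L, 50L), c(9L, 9L), c(4L, 5L)),
    conservation = branch_spec("conservation", c(20L, 40L, 60L), c(9L, 5L, 2L), c(3L, 4L, 5L))
  )
}

#' Model specification for an MRE scorer
#'
#' @param region `"UTR3"` or `"CDS"`.
#' @param branches character vector of branch names (subset for ablation) or
#'   a named list of [branch_spec()]s.
#' @param dense_nodes widths of the dense head (default `c(90, 55, 35)`).
#' @param dense_dropout dropout in the dense head (default 0.1).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs maximum training epochs (default 200).
#' @param early_stop_patience early-stopping patience in epochs (default 15).
#' @param batch_size minibatch size (default 64).
#' @param val_fraction stratified validation fraction for early stopping
#'   (default 0.1).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return a `model_spec` list.
#' @export
model_spec <- function(region = c("UTR3", "CDS"), branches = names(BRANCH_INPUTS),
                       dense_nodes = c(90L, 55L, 35L), dense_dropout = 0.1,
                       learning_rate = 1e-4, epochs = 200L,
                       early_stop_patience = 15L, batch_size = 64L,
                       val_fraction = 0.1, seed = 1L) {
  region <- match.arg(region)
  if (is.character(branches)) {
    branches <- default_branches()[branches]
    if (any(vapply(branches, is.null, logical(1L)))) stop("unknown branch name")
  }
  if (length(branches) < 1L) stop("at least one branch required")
  names(branches) <- vapply(branches, `[[`, character(1L), "name")
  structure(list(region = region, branches = branches,
                 dense_nodes = as.integer(dense_nodes),
                 dense_dropout = dense_dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "model_spec")
}

branch_arch <- function(bs) {
  input <- BRANCH_INPUTS[[bs$name]]
  L <- input[1L]; C <- input[2L]
  layers <- list()
  for (i in seq_along(bs$filters)) {
    k <- bs$kernels[i]; s <- bs$strides[i]; f <- bs$filters[i]
    Lout <- (L - k) %/% s + 1L
    if (L < k || Lout < 1L)
      stop(sprintf("branch '%s' conv layer %d: kernel %d, stride %d on length %d yields non-positive output",
                   bs$name, i, k, s, L))
    pooled <- Lout >= bs$pool_size
    Lp <- if (pooled) Lout %/% bs$pool_size else Lout
    layers[[i]] <- list(k = k, s = s, f = f, cin = C, lin = L,
                        lconv = Lout, pooled = pooled, lout = Lp)
    L <- Lp; C <- f
  }
  list(name = bs$name, input = input, layers = layers,
       gru_in = C, gru_t = L, gru_units = bs$gru_units, dropout = bs$dropout,
       flat = L * bs$gru_units)
}

#' Build an untrained MRE scorer
#'
#' Instantiates the per-branch conv/pool/GRU stacks and the dense head, with
#' Glorot-initialized weights (seeded from the spec).
#'
#' @param spec a [model_spec()].
#' @return object of class `mre_model` with an inspectable layer summary
#'   ([model_summary()]).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  arch <- lapply(spec$branches, branch_arch)
  set.seed(spec$seed)
  params <- list()
  for (b in arch) {
    pre <- b$name
    for (i in seq_along(b$layers)) {
      ly <- b$layers[[i]]
      params[[paste0(pre, ".c", i, ".W")]] <- glorot(ly$k * ly$cin, ly$f,
                                                     c(ly$k * ly$cin, ly$f))
      params[[paste0(pre, ".c", i, ".b")]] <- rep(0, ly$f)
      params[[paste0(pre, ".c", i, ".gamma")]] <- rep(1, ly$f)
      params[[paste0(pre, ".c", i, ".beta")]] <- rep(0, ly$f)
      params[[paste0(pre, ".c", i, ".rmean")]] <- rep(0, ly$f)
      params[[paste0(pre, ".c", i, ".rvar")]] <- rep(1, ly$f)
    }
    g <- gru_init(b$gru_in, b$gru_units)
    for (nm in names(g)) params[[paste0(pre, ".gru.", nm)]] <- g[[nm]]
  }
  din <- sum(vapply(arch, `[[`, numeric(1L), "flat"))
  widths <- spec$dense_nodes
  for (i in seq_along(widths)) {
    params[[paste0("d", i, ".W")]] <- glorot(din, widths[i])
    params[[paste0("d", i, ".b")]] <- rep(0, widths[i])
    params[[paste0("d", i, ".gamma")]] <- rep(1, widths[i])
    params[[paste0("d", i, ".beta")]] <- rep(0, widths[i])
    params[[paste0("d", i, ".rmean")]] <- rep(0, widths[i])
    params[[paste0("d", i, ".rvar")]] <- rep(1, widths[i])
    din <- widths[i]
  }
  params[["out.W"]] <- glorot(din, 1L)
  params[["out.b"]] <- 0
  structure(list(spec = spec, arch = arch, params = params, history = NULL),
            class = "mre_model")
}

#' Per-layer summary of a built model
#'
#' One row per layer with output length/channels; conv rows carry kernel,
#' stride and pool information. Attributes `dense_nodes`, `gru_units`,
#' `pool_size` and `dropout` restate the head configuration.
#'
#' @param model an `mre_model`.
#' @return data.frame layer table.
#' @export
model_summary <- function(model) {
  rows <- list()
  for (b in model$arch) {
    rows[[length(rows) + 1L]] <- data.frame(
      branch = b$name, layer = "input", type = "input",
      kernel = NA_integer_, stride = NA_integer_, pooled = NA,
      out_length = b$input[1L], out_channels = b$input[2L])
    for (i in seq_along(b$layers)) {
      ly <- b$layers[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        branch = b$name, layer = paste0("conv", i), type = "conv",
        kernel = ly$k, stride = ly$s, pooled = ly$pooled,
        out_length = ly$lconv, out_channels = ly$f)
      if (ly$pooled) {
        rows[[length(rows) + 1L]] <- data.frame(
          branch = b$name, layer = paste0("pool", i), type = "maxpool",
          kernel = 2L, stride = 2L, pooled = NA,
          out_length = ly$lout, out_channels = ly$f)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      branch = b$name, layer = "gru", type = "gru",
      kernel = NA_integer_, stride = NA_integer_, pooled = NA,
      out_length = b$gru_t, out_channels = b$gru_units)
  }
  widths <- model$spec$dense_nodes
  for (i in seq_along(widths)) {
    rows[[length(rows) + 1L]] <- data.frame(
      branch = "head", layer = paste0("dense", i), type = "dense",
      kernel = NA_integer_, stride = NA_integer_, pooled = NA,
      out_length = 1L, out_channels = widths[i])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    branch = "head", layer = "output", type = "sigmoid",
    kernel = NA_integer_, stride = NA_integer_, pooled = NA,
    out_length = 1L, out_channels = 1L)
  out <- do.call(rbind, rows)
  attr(out, "dense_nodes") <- widths
  attr(out, "gru_units") <- vapply(model$arch, `[[`, integer(1L), "gru_units")
  attr(out, "pool_size") <- 2L
  attr(out, "dropout") <- unique(vapply(model$arch, `[[`, numeric(1L), "dropout"))
  out
}

#' @export
print.mre_model <- function(x, ...) {
  cat(sprintf("<mre_model region=%s, %d branch(es): %s; %s>\n",
              x$spec$region, length(x$arch),
              paste(names(x$arch), collapse = ", "),
              if (is.null(x$history)) "untrained" else "trained"))
  invisible(x)
}

check_branch_shapes <- function(model, X) {
  for (b in model$arch) {
    if (is.null(X[[b$name]]))
      stop("missing input for branch '", b$name, "'")
    d <- dim(X[[b$name]])
    if (length(d) != 3L || d[2L] != b$input[1L] || d[3L] != b$input[2L])
      stop(sprintf("branch '%s' expects input %d x %d, got %s",
                   b$name, b$input[1L], b$input[2L],
                   paste(d[-1L], collapse = " x ")))
  }
}

# Full forward pass. Returns probabilities plus caches for backprop; during
# training, batch-norm running statistics are updated in `params` (returned).
model_forward <- function(model, X, training = FALSE) {
  params <- model$params
  caches <- list()
  flats <- list()
  for (b in model$arch) {
    pre <- b$name
    H <- X[[pre]]
    bcache <- list()
    for (i in seq_along(b$layers)) {
      ly <- b$layers[[i]]
      key <- paste0(pre, ".c", i)
      cf <- conv_forward(H, params[[paste0(key, ".W")]],
                         params[[paste0(key, ".b")]], ly$k, ly$s)
      d <- dim(cf$Y)
      Ym <- matrix(cf$Y, d[1L] * d[2L], d[3L])
      bn <- bn_forward(Ym, params[[paste0(key, ".gamma")]],
                       params[[paste0(key, ".beta")]],
                       params[[paste0(key, ".rmean")]],
                       params[[paste0(key, ".rvar")]], training)
      if (training) {
        params[[paste0(key, ".rmean")]] <- bn$rmean
        params[[paste0(key, ".rvar")]] <- bn$rvar
      }
      ac <- lrelu_forward(bn$Y)
      Ha <- array(ac$Y, d)
      if (ly$pooled) {
        pl <- pool_forward(Ha)
        H <- pl$Y
      } else pl <- NULL
      if (!ly$pooled) H <- Ha
      bcache[[i]] <- list(conv = cf, bn = bn, ac = ac, pool = pl, dimY = d)
    }
    dp <- drop_forward(H, b$dropout, training)
    gf <- gru_forward(dp$Y, pget(params, paste0(pre, ".gru.")))
    dg <- dim(gf$Y)
    flats[[pre]] <- matrix(gf$Y, dg[1L], dg[2L] * dg[3L])
    caches[[pre]] <- list(layers = bcache, drop = dp, gru = gf)
  }
  Z <- do.call(cbind, unname(flats))
  hcache <- list()
  for (i in seq_along(model$spec$dense_nodes)) {
    key <- paste0("d", i)
    Y <- add_bias(Z %*% params[[paste0(key, ".W")]], params[[paste0(key, ".b")]])
    bn <- bn_forward(Y, params[[paste0(key, ".gamma")]],
                     params[[paste0(key, ".beta")]],
                     params[[paste0(key, ".rmean")]],
                     params[[paste0(key, ".rvar")]], training)
    if (training) {
      params[[paste0(key, ".rmean")]] <- bn$rmean
      params[[paste0(key, ".rvar")]] <- bn$rvar
    }
    ac <- lrelu_forward(bn$Y)
    dp <- drop_forward(ac$Y, model$spec$dense_dropout, training)
    hcache[[i]] <- list(Z = Z, bn = bn, ac = ac, drop = dp)
    Z <- dp$Y
  }
  logits <- add_bias(Z %*% params[["out.W"]], params[["out.b"]])
  prob <- sigmoid(logits)
  list(prob = as.numeric(prob), params = params,
       cache = list(branches = caches, head = hcache, Zout = Z))
}

pget <- function(params, prefix) {
  sel <- startsWith(names(params), prefix)
  out <- params[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

# Backward pass for mean binary cross-entropy; returns flat gradient list
# keyed like `params` (trainable entries only).
model_backward <- function(model, X, y, fwd) {
  params <- fwd$params
  n <- length(y)
  grads <- list()
  dlogit <- matrix((fwd$prob - y) / n, n, 1L)
  grads[["out.W"]] <- crossprod(fwd$cache$Zout, dlogit)
  grads[["out.b"]] <- sum(dlogit)
  dZ <- tcrossprod(dlogit, params[["out.W"]])
  for (i in rev(seq_along(model$spec$dense_nodes))) {
    key <- paste0("d", i)
    hc <- fwd$cache$head[[i]]
    dZ <- drop_backward(dZ, hc$drop)
    dZ <- lrelu_backward(dZ, hc$ac)
    bb <- bn_backward(dZ, hc$bn, params[[paste0(key, ".gamma")]])
    grads[[paste0(key, ".gamma")]] <- bb$dgamma
    grads[[paste0(key, ".beta")]] <- bb$dbeta
    dY <- bb$dX
    grads[[paste0(key, ".W")]] <- crossprod(hc$Z, dY)
    grads[[paste0(key, ".b")]] <- colSums(dY)
    dZ <- tcrossprod(dY, params[[paste0(key, ".W")]])
  }
  # split concatenated gradient back to branches
  offset <- 0L
  for (b in model$arch) {
    pre <- b$name
    bc <- fwd$cache$branches[[pre]]
    w <- b$flat
    dF <- dZ[, (offset + 1L):(offset + w), drop = FALSE]
    offset <- offset + w
    dg <- array(dF, c(nrow(dF), b$gru_t, b$gru_units))
    gb <- gru_backward(dg, bc$gru, pget(params, paste0(pre, ".gru.")))
    for (nm in names(gb$grads))
      grads[[paste0(pre, ".gru.", nm)]] <- gb$grads[[nm]]
    dH <- drop_backward(gb$dX, bc$drop)
    for (i in rev(seq_along(b$layers))) {
      ly <- b$layers[[i]]
      lc <- bc$layers[[i]]
      if (ly$pooled) dH <- pool_backward(dH, lc$pool)
      d <- lc$dimY
      dHm <- matrix(dH, d[1L] * d[2L], d[3L])
      dHm <- lrelu_backward(dHm, lc$ac)
      key <- paste0(pre, ".c", i)
      bb <- bn_backward(dHm, lc$bn, params[[paste0(key, ".gamma")]])
      grads[[paste0(key, ".gamma")]] <- bb$dgamma
      grads[[paste0(key, ".beta")]] <- bb$dbeta
      dY <- array(bb$dX, d)
      cb <- conv_backward(dY, lc$conv, params[[paste0(key, ".W")]], ly$k, ly$s)
      grads[[paste0(key, ".W")]] <- cb$dW
      grads[[paste0(key, ".b")]] <- cb$db
      dH <- cb$dX
    }
  }
  grads
}

bce_loss <- function(prob, y, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

subset_X <- function(X, idx) lapply(X, function(a) a[idx, , , drop = FALSE])

#' Train an MRE scorer
#'
#' Minimizes binary cross-entropy with Adam; a stratified validation split
#' drives early stopping on validation loss, and the best-epoch weights are
#' restored. Fully reproducible for a fixed spec seed.
#'
#' @param model an untrained (or pre-trained) `mre_model` from
#'   [build_model()].
#' @param X either a list of `feature_bundle`s or the result of
#'   [stack_bundles()].
#' @param labels 0/1 vector, one per bundle; both classes required.
#' @param epochs optional override of `spec$epochs`.
#' @param verbose print per-epoch progress.
#' @return the trained `mre_model` with a `history` data.frame
#'   (`epoch`, `train_loss`, `val_loss`, `val_auc`).
#' @export
train_mre_model <- function(model, X, labels, epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "mre_model"))
  if (!is.list(X)) stop("X must be a bundle list or stacked arrays")
  if (length(X) && inherits(X[[1L]], "feature_bundle")) X <- stack_bundles(X)
  check_branch_shapes(model, X)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  n <- length(y)
  stopifnot(dim(X[[1L]])[1L] == n)
  spec <- model$spec
  if (is.null(epochs)) epochs <- spec$epochs
  set.seed(spec$seed + 1L)
  # stratified validation split
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    k <- max(1L, round(length(ix) * spec$val_fraction))
    sample(ix, k)
  }))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- subset_X(X, tr_idx); ytr <- y[tr_idx]
  Xva <- subset_X(X, val_idx); yva <- y[val_idx]
  opt <- adam_init(model$params[!grepl("\\.(rmean|rvar)$", names(model$params))])
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- list()
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(length(ytr))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next   # batch norm needs >= 2 observations
      fwd <- model_forward(model, subset_X(Xtr, idx), training = TRUE)
      model$params <- fwd$params  # running BN stats
      losses <- c(losses, bce_loss(fwd$prob, ytr[idx]))
      grads <- model_backward(model, NULL, ytr[idx], fwd)
      st <- adam_step(model$params[names(opt$m)], grads[names(opt$m)], opt,
                      spec$learning_rate)
      model$params[names(opt$m)] <- st$params
      opt <- st$state
      if (any(!is.finite(losses))) stop("NaN/Inf training loss at epoch ", ep)
    }
    pv <- score_mres(model, Xva)
    vloss <- bce_loss(pv, yva)
    vauc <- rank_auc(pv, yva)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                             val_loss = vloss, val_auc = vauc)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val_auc %.3f",
                      ep, mean(losses), vloss, vauc))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = model$params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch
  model
}

#' Score feature bundles with a trained model
#'
#' @param model an `mre_model`.
#' @param X bundle list or stacked arrays.
#' @param batch_size scoring batch size (results are batch-size invariant;
#'   inference uses running batch-norm statistics).
#' @return numeric vector of scores in \[0,1\], order preserved.
#' @export
score_mres <- function(model, X, batch_size = 256L) {
  if (length(X) && inherits(X[[1L]], "feature_bundle")) X <- stack_bundles(X)
  check_branch_shapes(model, X)
  n <- dim(X[[1L]])[1L]
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- model_forward(model, subset_X(X, idx), training = FALSE)$prob
  }
  out
}

#' Ablation variants of a model specification
#'
#' The five single-branch specs plus the standard combinations:
#' chimera+conservation, chimera+duplex, and all-minus-fold.
#'
#' @param full_spec a five-branch [model_spec()].
#' @return named list of `model_spec`s (8 variants).
#' @export
ablation_variants <- function(full_spec) {
  mk <- function(br) model_spec(region = full_spec$region, branches = br,
                                dense_nodes = full_spec$dense_nodes,
                                dense_dropout = full_spec$dense_dropout,
                                learning_rate = full_spec$learning_rate,
                                epochs = full_spec$epochs,
                                early_stop_patience = full_spec$early_stop_patience,
                                batch_size = full_spec$batch_size,
                                val_fraction = full_spec$val_fraction,
                                seed = full_spec$seed)
  singles <- lapply(names(BRANCH_INPUTS), mk)
  names(singles) <- paste0(names(BRANCH_INPUTS), "_only")
  c(singles,
    list("chimera+conservation" = mk(c("chimera", "conservation")),
         "chimera+duplex" = mk(c("chimera", "duplex")),
         "no_fold" = mk(c("mre", "chimera", "duplex", "conservation"))))
}

#' Serialize a trained model to a directory
#'
#' Writes `spec.json` (configuration) and `weights.rds` (parameters,
#' history). The directory layout is stable across package versions of the
#' same minor series.
#'
#' @param model an `mre_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mre_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- model$spec
  cfg <- list(region = spec$region,
              branches = lapply(spec$branches, function(b)
                b[c("name", "filters", "kernels", "strides", "pool_size",
                    "gru_units", "dropout")]),
              dense_nodes = spec$dense_nodes, dense_dropout = spec$dense_dropout,
              learning_rate = spec$learning_rate, epochs = spec$epochs,
              early_stop_patience = spec$early_stop_patience,
              batch_size = spec$batch_size, val_fraction = spec$val_fraction,
              seed = spec$seed)
  jsonlite::write_json(cfg, file.path(dir, "spec.json"), auto_unbox = TRUE)
  saveRDS(list(params = model$params, history = model$history,
               best_epoch = model$best_epoch),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a model written by [write_mre_model()]
#'
#' @param dir model directory.
#' @return an `mre_model`.
#' @export
read_mre_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  branches <- lapply(cfg$branches, function(b)
    branch_spec(b$name, b$filters, b$kernels, b$strides, b$pool_size,
                b$gru_units, b$dropout))
  spec <- model_spec(region = cfg$region, branches = branches,
                     dense_nodes = cfg$dense_nodes,
                     dense_dropout = cfg$dense_dropout,
                     learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                     early_stop_patience = cfg$early_stop_patience,
                     batch_size = cfg$batch_size,
                     val_fraction = cfg$val_fraction, seed = cfg$seed)
  model <- build_model(spec)
  blob <- readRDS(file.path(dir, "weights.rds"))
  model$params <- blob$params
  model$history <- blob$history
  model$best_epoch <- blob$best_epoch
  model
}
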