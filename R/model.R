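# Per-element feed-forward networks trained to map per-atom environment
# vectors to atomic pK contributions; the sum over atoms is the prediction.
# Implemented directly on base-R linear algebra: forward, reverse-mode
# gradients and ADAM are a few matrix products, and keeping them explicit is
# what lets the featurizer chain rule (coordinate gradients) stay exact.

#' Architecture of the atomic networks
#'
#' One feed-forward network per species, all sharing the same architecture:
#' rectifier activations, dropout after every hidden activation (inactive at
#' inference), a single linear output unit. Default 256-128-64-1 with 25%
#' dropout.
#'
#' @param input_size AEV length the networks consume.
#' @param n_species number of atomic networks.
#' @param hidden_sizes ordered hidden-layer widths.
#' @param activation only `"relu"` is implemented.
#' @param dropout_p dropout probability in \[0, 1).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(input_size, n_species,
                         hidden_sizes = c(256, 128, 64),
                         activation = "relu", dropout_p = 0.25) {
  stopifnot(input_size >= 1, n_species >= 1, length(hidden_sizes) >= 1,
            all(hidden_sizes >= 1), dropout_p >= 0, dropout_p < 1)
  activation <- match.arg(activation, "relu")
  structure(list(input_size = as.integer(input_size),
                 n_species = as.integer(n_species),
                 hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, dropout_p = dropout_p),
            class = "network_spec")
}

#' Training configuration
#'
#' Defaults: ADAM with learning rate 1e-4, beta1 = 0.9, beta2 = 0.999,
#' batch size 64, mean-squared-error loss on pK, 250 epochs with
#' best-validation-loss checkpointing. The seed fixes weight initialization,
#' shuffling and dropout, making runs bit-reproducible.
#'
#' @param learning_rate ADAM step size.
#' @param batch_size systems per minibatch.
#' @param max_epochs epoch budget.
#' @param loss only `"mse"` is implemented.
#' @param seed integer seed for the whole run.
#' @param adam_beta1,adam_beta2 ADAM moment decays, in (0, 1).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64,
                         max_epochs = 250, loss = "mse", seed = 1L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            adam_beta1 > 0, adam_beta1 < 1, adam_beta2 > 0, adam_beta2 < 1)
  loss <- match.arg(loss, "mse")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), loss = loss,
                 seed = as.integer(seed),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2),
            class = "train_config")
}

# uniform fan-in initialization for one stack of layers; draws from the
# current RNG stream
.init_net <- function(sizes) {
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    bound <- 1 / sqrt(fan_in)
    W[[l]] <- matrix(stats::runif(sizes[l + 1L] * fan_in, -bound, bound),
                     sizes[l + 1L], fan_in)
    b[[l]] <- stats::runif(sizes[l + 1L], -bound, bound)
  }
  list(W = W, b = b)
}

#' Initialize an untrained model
#'
#' @param spec a [network_spec()].
#' @param params the [aev_params()] the model consumes; stored with the
#'   model so the feature layout can never silently drift.
#' @param seed integer seed for weight initialization.
#' @return an object of class `aev_model`.
#' @export
init_model <- function(spec, params, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), inherits(params, "aev_params"))
  if (spec$n_species != length(params$species))
    stop("n_species must match length(params$species)")
  if (spec$input_size != aev_length(params))
    stop("input_size must equal aev_length(params)")
  sizes <- c(spec$input_size, spec$hidden_sizes, 1L)
  nets <- withr::with_seed(seed,
    lapply(seq_len(spec$n_species), function(s) .init_net(sizes)))
  structure(list(spec = spec, params = params, nets = nets),
            class = "aev_model")
}

#' @export
print.aev_model <- function(x, ...) {
  cat("aev_model:", x$spec$n_species, "atomic networks (",
      paste(x$params$species, collapse = " "), ")\n")
  cat("  architecture:", x$spec$input_size, "-",
      paste(x$spec$hidden_sizes, collapse = "-"), "- 1, dropout",
      x$spec$dropout_p, "\n")
  invisible(x)
}

# forward pass for a row-block X (n x d) through one net.
# masks: optional list of dropout masks per hidden layer (same dims as the
# activation); NULL means inference (dropout off).
# W is stored (out x in); tcrossprod avoids explicit transposes.
.forward_net <- function(net, X, masks = NULL) {
  nl <- length(net$W)
  A <- vector("list", nl + 1L)  # A[[1]] = input, A[[l+1]] = layer l output
  A[[1L]] <- X
  n <- nrow(X)
  for (l in seq_len(nl - 1L)) {
    Z <- tcrossprod(A[[l]], net$W[[l]]) + rep(net$b[[l]], each = n)
    Z[Z < 0] <- 0
    if (!is.null(masks)) Z <- Z * masks[[l]]
    A[[l + 1L]] <- Z
  }
  out <- drop(tcrossprod(A[[nl]], net$W[[nl]])) + net$b[[nl]]
  list(out = out, A = A)
}

# reverse pass: dout is d(loss)/d(out) per row. Returns parameter gradients
# and d(loss)/d(input).
.backward_net <- function(net, cache, dout, masks = NULL) {
  nl <- length(net$W)
  A <- cache$A
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  dO <- matrix(dout, ncol = 1L)
  gW[[nl]] <- crossprod(dO, A[[nl]])
  gb[[nl]] <- sum(dO)
  dA <- dO %*% net$W[[nl]]
  for (l in rev(seq_len(nl - 1L))) {
    if (!is.null(masks)) dA <- dA * masks[[l]]
    dZ <- dA * (A[[l + 1L]] > 0)
    gW[[l]] <- crossprod(dZ, A[[l]])
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% net$W[[l]]
  }
  list(gW = gW, gb = gb, dX = dA)
}

# propagate an AEV matrix through the per-species nets (inference).
# Returns per-atom contributions.
.contributions <- function(model, aevs, species_index) {
  aevs <- unclass(aevs)
  if (ncol(aevs) != model$spec$input_size)
    stop("AEV width ", ncol(aevs), " does not match model input width ",
         model$spec$input_size)
  if (any(species_index < 1L | species_index > model$spec$n_species))
    stop("species index outside the model's species range")
  contrib <- numeric(nrow(aevs))
  for (s in unique(species_index)) {
    rows <- which(species_index == s)
    contrib[rows] <- .forward_net(model$nets[[s]],
                                  aevs[rows, , drop = FALSE])$out
  }
  contrib
}

#' Predict binding affinity from atomic environment vectors
#'
#' Each AEV row is propagated through the atomic network of its species; the
#' per-atom outputs are the atomic contributions (pK units) and their sum is
#' the predicted pK. Dropout is inactive.
#'
#' @param object an `aev_model`.
#' @param aevs AEV matrix (rows = atoms), e.g. from [compute_aevs()].
#' @param species_index per-row species indices; defaults to the
#'   `species_index` attribute of `aevs`.
#' @param ... unused.
#' @return list of class `aev_prediction` with elements `pk` and
#'   `atomic_contributions`.
#' @export
predict.aev_model <- function(object, aevs,
                              species_index = attr(aevs, "species_index"),
                              ...) {
  if (is.null(species_index)) stop("species_index required")
  contrib <- .contributions(object, aevs, species_index)
  structure(list(pk = sum(contrib), atomic_contributions = contrib,
                 std = NA_real_),
            class = "aev_prediction")
}

#' @export
print.aev_prediction <- function(x, ...) {
  cat("predicted pK:", format(x$pk, digits = 4))
  if (!is.na(x$std)) cat(" +/-", format(x$std, digits = 3))
  cat("  (", length(x$atomic_contributions), "atomic contributions )\n")
  invisible(x)
}

#' Predict directly from an atomic system
#'
#' Convenience wrapper: featurizes with the model's own AEV parameters and
#' calls [predict.aev_model()].
#'
#' @param model an `aev_model` or `aev_ensemble`.
#' @param system an [atomic_system()].
#' @return an `aev_prediction`.
#' @export
predict_system <- function(model, system) {
  if (inherits(model, "aev_ensemble")) {
    aevs <- compute_aevs(system, model$models[[1]]$params)
    return(consensus_predict(model, aevs))
  }
  aevs <- compute_aevs(system, model$params)
  predict(model, aevs)
}

# gradient of the summed output w.r.t. each input row (dropout off);
# n x d matrix aligned with aevs
.input_gradient <- function(model, aevs, species_index) {
  aevs <- unclass(aevs)
  g <- matrix(0, nrow(aevs), ncol(aevs))
  for (s in unique(species_index)) {
    rows <- which(species_index == s)
    fw <- .forward_net(model$nets[[s]], aevs[rows, , drop = FALSE])
    bw <- .backward_net(model$nets[[s]], fw, rep(1, length(rows)))
    g[rows, ] <- bw$dX
  }
  g
}

# --- training ---------------------------------------------------------------

.adam_init <- function(nets) {
  lapply(nets, function(net) list(
    mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
    mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0)))
}

# one ADAM step on a single tensor; returns list(theta, m, v)
.adam_step <- function(theta, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(theta = theta - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# loss over a dataset (inference mode). ds: list of records with aevs,
# species, y.
.dataset_loss <- function(model, ds) {
  err <- vapply(ds, function(r)
    sum(.contributions(model, r$aevs, r$species)) - r$y, 0)
  mean(err^2)
}

#' Train the per-element network stack
#'
#' Minibatch gradient descent with ADAM on the mean-squared error between
#' predicted and experimental pK. Systems are shuffled each epoch; dropout
#' masks, shuffling and initialization all derive from `cfg$seed`, so two
#' runs with the same seed produce bit-identical histories. The parameters
#' achieving the best validation loss are returned.
#'
#' @param train_set,val_set lists of records `list(aevs, species, y)`, with
#'   `aevs` an AEV matrix, `species` per-row species indices and `y` the
#'   target pK (see [featurize_complexes()]).
#' @param spec a [network_spec()].
#' @param params the [aev_params()] used to featurize.
#' @param cfg a [train_config()].
#' @param verbose print one line per 25 epochs?
#' @return an `aev_model` with an added `history` element (data.frame with
#'   columns epoch, train_loss, val_loss) and `best_epoch`.
#' @export
train_model <- function(train_set, val_set, spec, params,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(length(train_set) >= 1, length(val_set) >= 1)
  model <- init_model(spec, params, seed = cfg$seed)
  # per-element baseline offset: start every atomic output at the per-atom
  # target mean, so the sum-pooled prediction starts at the dataset mean
  # (the analogue of atomic reference energies in neural-network potentials;
  # without it the output bias alone needs thousands of optimizer steps)
  ybar <- mean(vapply(train_set, function(r) r$y, 0))
  nbar <- mean(vapply(train_set, function(r) nrow(r$aevs), 0))
  for (s in seq_along(model$nets)) {
    nl <- length(model$nets[[s]]$b)
    model$nets[[s]]$b[[nl]] <- ybar / nbar
  }
  withr::with_seed(cfg$seed + 1L, {
    opt <- .adam_init(model$nets)
    t_step <- 0L
    n <- length(train_set)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    best <- list(loss = Inf, nets = model$nets, epoch = 0L)
    p_drop <- spec$dropout_p
    nl_hidden <- length(spec$hidden_sizes)
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        recs <- train_set[idx]
        X <- do.call(rbind, lapply(recs, function(r) unclass(r$aevs)))
        sp <- unlist(lapply(recs, function(r) r$species))
        sys_id <- rep(seq_along(recs), vapply(recs, function(r) nrow(r$aevs), 0L))
        y <- vapply(recs, function(r) r$y, 0)
        contrib <- numeric(nrow(X))
        caches <- list()
        masks_by_s <- list()
        for (s in unique(sp)) {
          rows <- which(sp == s)
          masks <- NULL
          if (p_drop > 0) {
            masks <- lapply(spec$hidden_sizes, function(h)
              matrix((stats::runif(length(rows) * h) >= p_drop) / (1 - p_drop),
                     length(rows), h))
          }
          fw <- .forward_net(model$nets[[s]], X[rows, , drop = FALSE], masks)
          contrib[rows] <- fw$out
          caches[[as.character(s)]] <- fw
          masks_by_s[[as.character(s)]] <- masks
        }
        pk <- as.vector(rowsum(contrib, sys_id))
        resid <- pk - y
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch,
               " (diverged; check targets and learning rate)")
        batch_losses <- c(batch_losses, loss)
        dpk <- 2 * resid / length(y)
        dout <- dpk[sys_id]
        t_step <- t_step + 1L
        for (s in unique(sp)) {
          rows <- which(sp == s)
          bw <- .backward_net(model$nets[[s]], caches[[as.character(s)]],
                              dout[rows], masks_by_s[[as.character(s)]])
          for (l in seq_along(model$nets[[s]]$W)) {
            up <- .adam_step(model$nets[[s]]$W[[l]], bw$gW[[l]],
                             opt[[s]]$mW[[l]], opt[[s]]$vW[[l]],
                             cfg$learning_rate, cfg$adam_beta1,
                             cfg$adam_beta2, t_step)
            model$nets[[s]]$W[[l]] <- up$theta
            opt[[s]]$mW[[l]] <- up$m
            opt[[s]]$vW[[l]] <- up$v
            up <- .adam_step(model$nets[[s]]$b[[l]], bw$gb[[l]],
                             opt[[s]]$mb[[l]], opt[[s]]$vb[[l]],
                             cfg$learning_rate, cfg$adam_beta1,
                             cfg$adam_beta2, t_step)
            model$nets[[s]]$b[[l]] <- up$theta
            opt[[s]]$mb[[l]] <- up$m
            opt[[s]]$vb[[l]] <- up$v
          }
        }
      }
      val_loss <- .dataset_loss(model, val_set)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     val_loss = val_loss))
      if (val_loss < best$loss)
        best <- list(loss = val_loss, nets = model$nets, epoch = epoch)
      if (verbose && epoch %% 25L == 0L)
        message(sprintf("epoch %4d  train %.4f  val %.4f",
                        epoch, mean(batch_losses), val_loss))
    }
    model$nets <- best$nets
    model$history <- hist
    model$best_epoch <- best$epoch
  })
  model
}

#' Train a consensus ensemble
#'
#' `k` models are independently initialized and trained (seeds
#' `cfg$seed + 0 .. k-1`); predictions are averaged and their spread
#' provides a per-prediction uncertainty.
#'
#' @inheritParams train_model
#' @param k ensemble size (default 5).
#' @return an object of class `aev_ensemble` (list of `aev_model`s).
#' @export
train_ensemble <- function(train_set, val_set, spec, params,
                           cfg = train_config(), k = 5L, verbose = FALSE) {
  stopifnot(k >= 1)
  models <- lapply(seq_len(k) - 1L, function(off) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + off
    train_model(train_set, val_set, spec, params, cfg_i, verbose = verbose)
  })
  structure(list(models = models), class = "aev_ensemble")
}

#' Consensus prediction of an ensemble
#'
#' The ensemble pK is the mean of the member predictions; the reported
#' uncertainty is their population standard deviation (zero for a single
#' member or identical members). Atomic contributions are averaged.
#'
#' @param ensemble an `aev_ensemble`, or plain list of `aev_model`s.
#' @param aevs AEV matrix.
#' @param species_index per-row species indices (defaults to the attribute).
#' @return an `aev_prediction` with `std` set and a `member_pk` element.
#' @export
consensus_predict <- function(ensemble, aevs,
                              species_index = attr(aevs, "species_index")) {
  models <- if (inherits(ensemble, "aev_ensemble")) ensemble$models else ensemble
  if (length(models) == 0L) stop("empty ensemble")
  preds <- lapply(models, function(m) predict(m, aevs, species_index))
  pks <- vapply(preds, function(p) p$pk, 0)
  contrib <- Reduce(`+`, lapply(preds, function(p) p$atomic_contributions)) /
    length(preds)
  structure(list(pk = mean(pks),
                 std = sqrt(mean((pks - mean(pks))^2)),
                 atomic_contributions = contrib,
                 member_pk = pks),
            class = "aev_prediction")
}

#' Featurize complexes into a training set
#'
#' Applies binding-site selection and AEV computation to each complex,
#' producing the record list consumed by [train_model()].
#'
#' @param complexes list of [pl_complex()] objects.
#' @param params an [aev_params()].
#' @param d selection distance, Angstrom.
#' @param map a [species_map()]; its canonical species must equal
#'   `params$species`.
#' @param targets optional numeric targets overriding each complex's
#'   `pk_exp` (used for delta-learning residuals).
#' @return list of records `list(aevs, species, y, id)`.
#' @export
featurize_complexes <- function(complexes, params, d = 3.5,
                                map = species_map(), targets = NULL) {
  if (!identical(map$canonical_species, params$species))
    stop("species_map canonical species must match aev_params species")
  lapply(seq_along(complexes), function(i) {
    cx <- complexes[[i]]
    sys <- select_binding_site(cx, d = d, map = map)
    aevs <- compute_aevs(sys, params)
    y <- if (is.null(targets)) cx$pk_exp else targets[i]
    list(aevs = aevs, species = attr(aevs, "species_index"), y = y, id = cx$id)
  })
}

# --- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Self-describing JSON archive: architecture, AEV parameters, species order
#' and all weights, so the feature layout a model was trained on can never
#' drift silently.
#'
#' @param model an `aev_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "aev_model"))
  payload <- list(
    format = "aevbind-checkpoint-1",
    spec = unclass(model$spec),
    aev_params = unclass(model$params),
    nets = lapply(model$nets, function(net)
      list(W = lapply(net$W, function(w) unclass(w)),
           b = net$b)))
  writeLines(as.character(jsonlite::toJSON(payload, digits = NA,
                                           auto_unbox = TRUE)), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return an `aev_model`.
#' @export
load_checkpoint <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  if (!identical(x$format, "aevbind-checkpoint-1"))
    stop("not an aevbind checkpoint: ", path)
  params <- aev_params(species = x$aev_params$species,
                       Rc_radial = x$aev_params$Rc_radial,
                       eta_R = x$aev_params$eta_R,
                       radial_shifts = x$aev_params$radial_shifts,
                       Rc_angular = x$aev_params$Rc_angular,
                       eta_A = x$aev_params$eta_A,
                       angular_radial_shifts = x$aev_params$angular_radial_shifts,
                       theta_shifts = x$aev_params$theta_shifts,
                       zeta = x$aev_params$zeta)
  spec <- network_spec(input_size = x$spec$input_size,
                       n_species = x$spec$n_species,
                       hidden_sizes = x$spec$hidden_sizes,
                       activation = x$spec$activation,
                       dropout_p = x$spec$dropout_p)
  nets <- lapply(x$nets, function(net)
    list(W = lapply(net$W, as.matrix), b = lapply(net$b, as.numeric)))
  structure(list(spec = spec, params = params, nets = nets),
            class = "aev_model")
}
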