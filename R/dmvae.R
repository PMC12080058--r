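# Disentangled multi-modal variational autoencoder (DMVAE).
#
# One encoder and one decoder per modality. Each encoder produces a
# posterior over a *shared* latent (common to all modalities) and over a
# *private* latent (specific to its modality). Decoders are trained with
# self- and cross-modal reconstruction: decoder m reconstructs x_m from the
# shared code of every modality n paired with m's own private code, which
# forces the shared space to carry cross-modal structure. Gaussian
# likelihood with a learned per-feature log-variance; KL terms for every
# shared and private posterior against N(0, I).
#
# Implemented directly with base matrix operations (2-layer ReLU MLPs,
# reparameterisation trick, Adam) so training is fully deterministic under a
# fixed seed.

LOGVAR_CLAMP <- 8

#' Construct an untrained multi-modal normative model
#'
#' @param modalities Named list of [modality_spec()] objects declaring the
#'   feature blocks.
#' @param k_shared Shared latent dimension.
#' @param k_private Private latent dimension per modality.
#' @param hidden Hidden-layer width of every encoder/decoder MLP.
#' @param seed Integer seed used for weight initialization (and as default
#'   training seed).
#' @return An object of class `normative_model`.
#' @export
dmvae_model <- function(modalities, k_shared = 10, k_private = 2,
                        hidden = 64, seed = 1L) {
  stopifnot(length(modalities) >= 1, k_shared >= 1, k_private >= 0)
  seed <- as.integer(seed)
  params <- with_seed(seed, {
    lapply(modalities, function(ms) {
      d <- length(ms$features)
      init_modality_params(d, hidden, k_shared, k_private)
    })
  })
  structure(list(modalities = modalities, k_s = k_shared, k_p = k_private,
                 hidden = hidden, params = params,
                 history = data.frame(phase = character(),
                                      epoch = integer(), loss = numeric()),
                 hyper = list(), seed = seed, trained = FALSE),
            class = "normative_model")
}

init_modality_params <- function(d, h, ks, kp) {
  rmat <- function(a, b, sd) matrix(stats::rnorm(a * b, sd = sd), a, b)
  list(
    enc = list(
      W1 = rmat(d, h, sqrt(2 / d)), b1 = numeric(h),
      Ws = rmat(h, ks, sqrt(1 / h)), bs = numeric(ks),
      Wsv = rmat(h, ks, 0.01), bsv = rep(-3, ks),
      Wp = rmat(h, max(kp, 1), sqrt(1 / h))[, seq_len(kp), drop = FALSE],
      bp = numeric(kp),
      Wpv = rmat(h, max(kp, 1), 0.01)[, seq_len(kp), drop = FALSE],
      bpv = rep(-3, kp)),
    dec = list(
      V1 = rmat(ks + kp, h, sqrt(2 / (ks + kp))), c1 = numeric(h),
      V2 = rmat(h, d, sqrt(1 / h)), c2 = numeric(d),
      s = numeric(d)))  # per-feature observation log-variance
}

#' @export
print.normative_model <- function(x, ...) {
  dims <- vapply(x$modalities, function(m) length(m$features), 0L)
  cat(sprintf(
    "<normative_model> %s | k_shared=%d, k_private=%d, hidden=%d | %s\n",
    paste(sprintf("%s(%d)", names(dims), dims), collapse = " + "),
    x$k_s, x$k_p, x$hidden,
    if (x$trained) sprintf("trained (%d epochs logged)", nrow(x$history))
    else "untrained"))
  invisible(x)
}

relu <- function(x) (x > 0) * x

enc_forward <- function(pe, X) {
  H <- relu(sweep(X %*% pe$W1, 2, pe$b1, `+`))
  clamp <- function(v) pmin(pmax(v, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  lvs_raw <- sweep(H %*% pe$Wsv, 2, pe$bsv, `+`)
  lvp_raw <- if (ncol(pe$Wp) > 0) sweep(H %*% pe$Wpv, 2, pe$bpv, `+`)
             else matrix(0, nrow(X), 0)
  list(H = H,
       mu_s = sweep(H %*% pe$Ws, 2, pe$bs, `+`),
       lv_s = clamp(lvs_raw), lvs_in = abs(lvs_raw) < LOGVAR_CLAMP,
       mu_p = if (ncol(pe$Wp) > 0) sweep(H %*% pe$Wp, 2, pe$bp, `+`)
              else matrix(0, nrow(X), 0),
       lv_p = clamp(lvp_raw), lvp_in = abs(lvp_raw) < LOGVAR_CLAMP)
}

dec_forward <- function(pd, Z) {
  G <- relu(sweep(Z %*% pd$V1, 2, pd$c1, `+`))
  list(G = G, Xhat = sweep(G %*% pd$V2, 2, pd$c2, `+`))
}

zero_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

# One minibatch: returns loss and gradients (same nested shape as params).
dmvae_step <- function(params, Xs, beta) {
  M <- length(params)
  B <- nrow(Xs[[1]])
  grads <- lapply(params, function(pm) lapply(pm, lapply, zero_like))

  enc <- lapply(seq_len(M), function(m) enc_forward(params[[m]]$enc, Xs[[m]]))
  eps_s <- lapply(enc, function(e) matrix(stats::rnorm(length(e$mu_s)),
                                          nrow(e$mu_s), ncol(e$mu_s)))
  eps_p <- lapply(enc, function(e) matrix(stats::rnorm(length(e$mu_p)),
                                          nrow(e$mu_p), ncol(e$mu_p)))
  z_s <- lapply(seq_len(M), function(m)
    enc[[m]]$mu_s + eps_s[[m]] * exp(0.5 * enc[[m]]$lv_s))
  z_p <- lapply(seq_len(M), function(m)
    enc[[m]]$mu_p + eps_p[[m]] * exp(0.5 * enc[[m]]$lv_p))

  ks <- ncol(z_s[[1]])
  dz_s <- lapply(z_s, zero_like)
  dz_p <- lapply(z_p, zero_like)
  loss <- 0
  w <- 1 / M  # average the M shared-code sources per decoder

  for (m in seq_len(M)) {
    pd <- params[[m]]$dec
    Xm <- Xs[[m]]
    inv_var <- exp(-pd$s)
    for (n in seq_len(M)) {
      Z <- cbind(z_s[[n]], z_p[[m]])
      fw <- dec_forward(pd, Z)
      R <- fw$Xhat - Xm
      loss <- loss + w * sum(0.5 * (sweep(R^2, 2, inv_var, `*`) +
                                      rep(pd$s + log(2 * pi),
                                          each = B))) / B
      dXhat <- sweep(R, 2, inv_var, `*`) * (w / B)
      grads[[m]]$dec$s <- grads[[m]]$dec$s +
        (w / B) * 0.5 * colSums(1 - sweep(R^2, 2, inv_var, `*`))
      dG <- (dXhat %*% t(pd$V2)) * (fw$G > 0)
      grads[[m]]$dec$V2 <- grads[[m]]$dec$V2 + t(fw$G) %*% dXhat
      grads[[m]]$dec$c2 <- grads[[m]]$dec$c2 + colSums(dXhat)
      grads[[m]]$dec$V1 <- grads[[m]]$dec$V1 + t(Z) %*% dG
      grads[[m]]$dec$c1 <- grads[[m]]$dec$c1 + colSums(dG)
      dZ <- dG %*% t(pd$V1)
      dz_s[[n]] <- dz_s[[n]] + dZ[, seq_len(ks), drop = FALSE]
      if (ncol(z_p[[m]]) > 0) {
        dz_p[[m]] <- dz_p[[m]] + dZ[, -seq_len(ks), drop = FALSE]
      }
    }
  }

  for (m in seq_len(M)) {
    e <- enc[[m]]
    kl <- 0.5 * (sum(e$mu_s^2 + exp(e$lv_s) - e$lv_s - 1) +
                   sum(e$mu_p^2 + exp(e$lv_p) - e$lv_p - 1)) / B
    loss <- loss + beta * kl

    dmu_s <- dz_s[[m]] + beta * e$mu_s / B
    dlv_s <- (dz_s[[m]] * eps_s[[m]] * 0.5 * exp(0.5 * e$lv_s) +
                beta * 0.5 * (exp(e$lv_s) - 1) / B) * e$lvs_in
    dmu_p <- dz_p[[m]] + beta * e$mu_p / B
    dlv_p <- (dz_p[[m]] * eps_p[[m]] * 0.5 * exp(0.5 * e$lv_p) +
                beta * 0.5 * (exp(e$lv_p) - 1) / B) * e$lvp_in

    pe <- params[[m]]$enc
    dH <- dmu_s %*% t(pe$Ws) + dlv_s %*% t(pe$Wsv)
    if (ncol(e$mu_p) > 0) {
      dH <- dH + dmu_p %*% t(pe$Wp) + dlv_p %*% t(pe$Wpv)
    }
    dH <- dH * (e$H > 0)
    g <- grads[[m]]$enc
    g$W1 <- g$W1 + t(Xs[[m]]) %*% dH;      g$b1 <- g$b1 + colSums(dH)
    g$Ws <- g$Ws + t(e$H) %*% dmu_s;       g$bs <- g$bs + colSums(dmu_s)
    g$Wsv <- g$Wsv + t(e$H) %*% dlv_s;     g$bsv <- g$bsv + colSums(dlv_s)
    if (ncol(e$mu_p) > 0) {
      g$Wp <- g$Wp + t(e$H) %*% dmu_p;     g$bp <- g$bp + colSums(dmu_p)
      g$Wpv <- g$Wpv + t(e$H) %*% dlv_p;   g$bpv <- g$bpv + colSums(dlv_p)
    }
    grads[[m]]$enc <- g
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params) {
  lapply(params, function(pm) lapply(pm, function(blk)
    lapply(blk, function(x) list(m = zero_like(x), v = zero_like(x)))))
}

adam_update <- function(params, grads, state, lr, t,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (m in names(params)) for (blk in names(params[[m]])) {
    for (nm in names(params[[m]][[blk]])) {
      g <- grads[[m]][[blk]][[nm]]
      st <- state[[m]][[blk]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      params[[m]][[blk]][[nm]] <- params[[m]][[blk]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[m]][[blk]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

# Split confound-adjusted cohort features into per-modality matrices.
modality_matrices <- function(model, data) {
  lapply(model$modalities, function(ms) cohort_features(data, ms$features))
}

#' Train the normative model on a healthy cohort
#'
#' Optimizes the DMVAE objective — per-modality Gaussian reconstruction
#' likelihood (self- and cross-modal through the shared code) plus KL terms
#' for all shared and private posteriors — with Adam. Features are expected
#' to be confound-adjusted z-scores (see [apply_confound_model()]).
#'
#' @param model A [dmvae_model()] (or previously trained model).
#' @param data Cohort `data.frame` containing all model feature columns.
#' @param epochs Number of passes over the data (0 = no-op).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param beta KL weight.
#' @param kl_anneal Epochs over which beta is linearly ramped from 0
#'   (0 = no annealing).
#' @param seed Training seed (shuffling, reparameterisation noise).
#' @param phase Label recorded in the training history.
#' @return The trained `normative_model` with history appended.
#' @export
dmvae_train <- function(model, data, epochs = 100, batch_size = 256,
                        lr = 1e-3, beta = 1, kl_anneal = 0,
                        seed = model$seed, phase = "pretrain") {
  stopifnot(inherits(model, "normative_model"))
  if (epochs == 0) return(model)
  Xs <- modality_matrices(model, data)
  n <- nrow(Xs[[1]])
  params <- model$params
  state <- adam_init(params)
  hist <- vector("list", epochs)
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      beta_ep <- if (kl_anneal > 0) beta * min(1, ep / kl_anneal) else beta
      ord <- sample.int(n)
      splits <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (b in splits) {
        Xb <- lapply(Xs, function(X) X[b, , drop = FALSE])
        st <- dmvae_step(params, Xb, beta_ep)
        if (!is.finite(st$loss)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (phase %s); %s",
            ep, phase, "reduce the learning rate or check input scaling"))
        }
        t <- t + 1
        up <- adam_update(params, st$grads, state, lr, t)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + st$loss * length(b)
      }
      hist[[ep]] <- data.frame(phase = phase, epoch = ep,
                               loss = ep_loss / n)
    }
  })
  model$params <- params
  model$history <- rbind(model$history, do.call(rbind, hist))
  model$hyper[[phase]] <- list(epochs = epochs, batch_size = batch_size,
                               lr = lr, beta = beta, kl_anneal = kl_anneal,
                               seed = seed, n = n)
  model$trained <- TRUE
  model
}

#' Fine-tune a pretrained model on target-site controls
#'
#' Continues optimization of *all* weights from the pretrained state (no
#' re-initialization) at a reduced learning rate, the usual transfer-learning
#' recipe for adapting a normative model trained at one site to the
#' acquisition/processing characteristics of another. The target-site data
#' must be adjusted with the target site's own confound model.
#'
#' @inheritParams dmvae_train
#' @param site_controls Confound-adjusted control cohort from the target
#'   site.
#' @return The fine-tuned `normative_model`.
#' @export
dmvae_finetune <- function(model, site_controls, epochs = 30,
                           batch_size = 256, lr = 1e-4, beta = 1,
                           seed = model$seed + 1L) {
  stopifnot(inherits(model, "normative_model"))
  if (!model$trained) stop("fine-tuning requires a trained model")
  missing <- setdiff(feature_names(model$modalities), names(site_controls))
  if (length(missing) > 0) {
    stop("site_controls lack model features: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  dmvae_train(model, site_controls, epochs = epochs,
              batch_size = batch_size, lr = lr, beta = beta, seed = seed,
              phase = "finetune")
}

#' Encode a cohort to latent posterior means
#'
#' Deterministic inference: no sampling. Each modality's encoder yields a
#' shared and a private posterior; the subject's single shared code is the
#' precision-weighted (product-of-experts) combination of the per-modality
#' shared posteriors.
#'
#' @param model A trained `normative_model`.
#' @param data Cohort `data.frame` with all model feature columns.
#' @return List with `shared` (n x k_shared matrix of posterior means),
#'   `shared_logvar`, and per-modality `private` / `private_logvar` lists.
#' @export
dmvae_encode <- function(model, data) {
  stopifnot(inherits(model, "normative_model"))
  Xs <- modality_matrices(model, data)
  enc <- lapply(seq_along(Xs), function(m)
    enc_forward(model$params[[m]]$enc, Xs[[m]]))
  prec <- lapply(enc, function(e) exp(-e$lv_s))
  Tprec <- Reduce(`+`, prec)
  shared <- Reduce(`+`, lapply(seq_along(enc), function(m)
    enc[[m]]$mu_s * prec[[m]])) / Tprec
  list(shared = shared, shared_logvar = -log(Tprec),
       private = stats::setNames(lapply(enc, `[[`, "mu_p"), names(Xs)),
       private_logvar = stats::setNames(lapply(enc, `[[`, "lv_p"),
                                        names(Xs)))
}

#' Reconstruct cohort features through the model
#'
#' Decodes each modality from the product-of-experts shared posterior mean
#' combined with that modality's private posterior mean.
#'
#' @inheritParams dmvae_encode
#' @return Numeric matrix (subjects x features) with the model's feature
#'   names and ordering.
#' @export
dmvae_reconstruct <- function(model, data) {
  code <- dmvae_encode(model, data)
  out <- lapply(seq_along(model$modalities), function(m) {
    Z <- cbind(code$shared, code$private[[m]])
    dec_forward(model$params[[m]]$dec, Z)$Xhat
  })
  out <- do.call(cbind, out)
  colnames(out) <- feature_names(model$modalities)
  out
}

#' Reconstruction residuals and mean squared reconstruction error
#'
#' Residuals are `input - reconstruction`, so a feature smaller than its
#' normative reconstruction (e.g. atrophy) gives a negative residual.
#'
#' @inheritParams dmvae_encode
#' @return `reconstruction_residuals()`: matrix of residuals with the input
#'   features' names; `reconstruction_error()`: overall mean squared error.
#' @export
reconstruction_residuals <- function(model, data) {
  feats <- feature_names(model$modalities)
  cohort_features(data, feats) - dmvae_reconstruct(model, data)
}

#' @rdname reconstruction_residuals
#' @export
reconstruction_error <- function(model, data) {
  mean(reconstruction_residuals(model, data)^2)
}

#' Save / load a normative model checkpoint
#'
#' Self-describing single-file container (architecture, weights, history,
#' seed); the round-trip is bit-exact.
#'
#' @param model A `normative_model`.
#' @param path File path.
#' @export
save_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_normative_model
#' @export
load_normative_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "normative_model"))
  model
}
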