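#' Build a dense autoencoder for gene-distribution images
#'
#' Fully-connected symmetric autoencoder: flattened binary image ->
#' ReLU hidden layers -> linear latent code of length `latent_dim`;
#' the decoder mirrors the encoder and ends in a sigmoid so reconstructions
#' live in \[0, 1\]. Initialization is He-scaled Gaussian under `seed`, so
#' identical seeds give bit-identical parameters.
#'
#' @param input_shape Integer pair (rows, cols) of the raster the model
#'   consumes.
#' @param latent_dim Latent code length d, default 128.
#' @param hidden Integer vector of encoder hidden-layer widths (mirrored in
#'   the decoder), default `c(256)`.
#' @param seed Integer seed for parameter initialization.
#' @return An `AutoencoderModel` (list of layer parameter matrices plus the
#'   architecture descriptor).
#' @export
build_autoencoder <- function(input_shape, latent_dim = 128L,
                              hidden = c(256L), seed = 1L) {
  input_dim <- as.integer(prod(input_shape))
  if (latent_dim < 1) gsi_stop("latent_dim must be >= 1")
  if (latent_dim >= input_dim)
    gsi_stop("latent_dim (", latent_dim, ") must be < flattened input size (",
             input_dim, ")")
  enc_sizes <- c(input_dim, as.integer(hidden), as.integer(latent_dim))
  dec_sizes <- rev(enc_sizes)
  enc_act <- c(rep("relu", length(hidden)), "linear")
  dec_act <- c(rep("relu", length(hidden)), "sigmoid")
  make_layers <- function(sizes, acts) {
    lapply(seq_along(acts), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1]),
           b = numeric(sizes[l + 1]),
           act = acts[l])
    })
  }
  with_seed(seed, {
    enc <- make_layers(enc_sizes, enc_act)
    dec <- make_layers(dec_sizes, dec_act)
    structure(list(input_shape = as.integer(input_shape),
                   input_dim = input_dim, latent_dim = as.integer(latent_dim),
                   hidden = as.integer(hidden), enc = enc, dec = dec,
                   seed = as.integer(seed)),
              class = "AutoencoderModel")
  })
}

#' @export
print.AutoencoderModel <- function(x, ...) {
  cat("AutoencoderModel:", paste(x$input_shape, collapse = "x"), "->",
      paste(c(x$hidden, x$latent_dim), collapse = " -> "),
      "(dense, seed", paste0(x$seed, ")\n"))
  invisible(x)
}

apply_act <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         gsi_stop("unknown activation: ", act))
}

act_grad <- function(a, act) {
  switch(act,
         relu = (a > 0) * 1,
         linear = 1,
         sigmoid = a * (1 - a))
}

mlp_forward <- function(layers, X) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (l in seq_along(layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- apply_act(z, layers[[l]]$act)
  }
  acts
}

# Backpropagate dL/d(output) through a layer list; returns gradients and
# dL/d(input) for chaining through encoder <- decoder.
mlp_backward <- function(layers, acts, d_out) {
  grads <- vector("list", length(layers))
  dA <- d_out
  for (l in rev(seq_along(layers))) {
    dZ <- dA * act_grad(acts[[l + 1]], layers[[l]]$act)
    grads[[l]] <- list(W = crossprod(acts[[l]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  list(grads = grads, d_in = dA)
}

flatten_stacks <- function(stacks) {
  if (inherits(stacks, "GeneImageStack")) stacks <- list(stacks)
  shp <- dim(stacks[[1]]$images)[2:3]
  rows <- lapply(stacks, function(st) {
    if (!all(dim(st$images)[2:3] == shp))
      gsi_stop("all stacks must share one raster shape")
    matrix(st$images, nrow = dim(st$images)[1])
  })
  do.call(rbind, rows)
}

#' Train the autoencoder on one or more image stacks
#'
#' Minimizes mean squared reconstruction error -- the mean over images of
#' the per-image pixel-wise MSE -- with Adam on shuffled minibatches. One
#' model is trained per integration group on the union of all member
#' samples' gene images. Fully deterministic under a fixed seed
#' (single-threaded BLAS assumed).
#'
#' @param stacks A `GeneImageStack` or list of them (same raster shape).
#' @param epochs Number of passes over the data, default 50.
#' @param lr Adam learning rate, default 1e-3.
#' @param batch_size Minibatch size, default 128.
#' @param seed Integer seed (initialization + shuffling).
#' @param latent_dim,hidden Architecture, passed to [build_autoencoder()]
#'   when `model` is NULL.
#' @param model Optional pre-built model to continue training.
#' @param verbose Print the loss every 10 epochs.
#' @return A `TrainingResult`: list with `model`, `loss_history` (full-data
#'   loss after each epoch), `epochs`.
#' @export
train_autoencoder <- function(stacks, epochs = 50L, lr = 1e-3,
                              batch_size = 128L, seed = 1L,
                              latent_dim = 128L, hidden = c(256L),
                              model = NULL, verbose = FALSE) {
  X <- flatten_stacks(stacks)
  if (inherits(stacks, "GeneImageStack")) stacks <- list(stacks)
  shp <- dim(stacks[[1]]$images)[2:3]
  if (is.null(model)) {
    model <- build_autoencoder(shp, latent_dim = latent_dim, hidden = hidden,
                               seed = seed)
  }
  if (model$input_dim != ncol(X))
    gsi_stop("model input size (", model$input_dim,
             ") != flattened image size (", ncol(X), ")")
  n <- nrow(X)
  layers <- c(model$enc, model$dec)
  adam <- lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  loss_history <- numeric(epochs)

  full_loss <- function() {
    acts <- mlp_forward(layers, X)
    mean((acts[[length(acts)]] - X)^2)
  }

  with_seed(derive_seed(seed, "ae-shuffle"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        acts <- mlp_forward(layers, Xb)
        Y <- acts[[length(acts)]]
        loss <- mean((Y - Xb)^2)
        if (!is.finite(loss))
          gsi_stop("non-finite training loss at epoch ", ep,
                   " (lr too high or degenerate input)")
        d_out <- 2 * (Y - Xb) / length(Xb)
        bp <- mlp_backward(layers, acts, d_out)
        t_step <- t_step + 1
        for (l in seq_along(layers)) {
          g <- bp$grads[[l]]
          a <- adam[[l]]
          a$mW <- beta1 * a$mW + (1 - beta1) * g$W
          a$vW <- beta2 * a$vW + (1 - beta2) * g$W^2
          a$mb <- beta1 * a$mb + (1 - beta1) * g$b
          a$vb <- beta2 * a$vb + (1 - beta2) * g$b^2
          mhW <- a$mW / (1 - beta1^t_step); vhW <- a$vW / (1 - beta2^t_step)
          mhb <- a$mb / (1 - beta1^t_step); vhb <- a$vb / (1 - beta2^t_step)
          layers[[l]]$W <- layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
          layers[[l]]$b <- layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
          adam[[l]] <- a
        }
      }
      loss_history[ep] <- full_loss()
      if (verbose && ep %% 10 == 0)
        message(sprintf("epoch %d: loss %.6f", ep, loss_history[ep]))
    }
  })
  n_enc <- length(model$enc)
  model$enc <- layers[seq_len(n_enc)]
  model$dec <- layers[(n_enc + 1):length(layers)]
  structure(list(model = model, loss_history = loss_history,
                 epochs = as.integer(epochs)),
            class = "TrainingResult")
}

#' Encode an image stack into spatial embeddings
#'
#' @param stack A `GeneImageStack` whose raster shape matches the model.
#' @param model A trained `AutoencoderModel`.
#' @return A `SpatialEmbedding`: list with `H` (N_gene x d matrix, rownames
#'   = gene IDs), `gene_ids`, `sample_id`.
#' @export
encode <- function(stack, model) {
  stopifnot(inherits(stack, "GeneImageStack"),
            inherits(model, "AutoencoderModel"))
  if (!all(dim(stack$images)[2:3] == model$input_shape))
    gsi_stop("stack raster shape does not match model input shape")
  X <- matrix(stack$images, nrow = dim(stack$images)[1])
  acts <- mlp_forward(model$enc, X)
  H <- acts[[length(acts)]]
  if (any(!is.finite(H))) gsi_stop("non-finite embedding values")
  rownames(H) <- stack$gene_ids
  colnames(H) <- paste0("emb_", seq_len(ncol(H)))
  structure(list(H = H, gene_ids = stack$gene_ids,
                 sample_id = stack$sample_id,
                 latent_dim = model$latent_dim),
            class = "SpatialEmbedding")
}

#' Decode latent codes back to images (diagnostics)
#'
#' @param H Matrix of latent codes (n x d).
#' @param model A trained `AutoencoderModel`.
#' @return 3D array n x rows x cols of reconstructions in \[0, 1\].
#' @export
decode <- function(H, model) {
  stopifnot(inherits(model, "AutoencoderModel"))
  H <- rbind(H)
  acts <- mlp_forward(model$dec, H)
  Y <- acts[[length(acts)]]
  array(Y, dim = c(nrow(H), model$input_shape))
}
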