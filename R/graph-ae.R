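# Graph-conditioned autoencoder over per-atom GIE-RC features, the naive
# whole-tensor autoencoder baseline, torsion-space conformer clustering and
# latent-space interpolation.

.vocab <- list(
  z = c("1", "6", "7", "8", "15", "16", "OTHER"),
  degree = c("1", "2", "3", "4", "5", "6"),
  charge = c("-1", "0", "1", "OTHER"),
  chirality = c("none", "R", "S", "OTHER"),
  hybridization = c("sp", "sp2", "sp3", "OTHER"),
  bond = c("1", "2", "3", "OTHER")
)

one_hot <- function(val, vocab) {
  idx <- match(as.character(val), vocab)
  idx[is.na(idx)] <- match("OTHER", vocab)
  m <- matrix(0, length(val), length(vocab), dimnames = list(NULL, vocab))
  m[cbind(seq_along(val), idx)] <- 1
  m
}

#' One-hot node and edge features of a molecular graph
#'
#' Node features concatenate one-hot blocks for atomic number, degree,
#' formal charge, chirality and hybridization (values outside the vocabulary
#' map to an explicit OTHER slot); edge features one-hot encode the bond
#' order.
#'
#' @param g molecular_graph.
#' @return list(node = N x d_v matrix, edge = n_bonds x d_e matrix).
#' @export
featurize <- function(g) {
  deg <- lengths(neighbors_list(g))
  node <- cbind(one_hot(g$atomic_numbers, .vocab$z),
                one_hot(deg, .vocab$degree),
                one_hot(g$formal_charges, .vocab$charge),
                one_hot(g$chirality_tags, .vocab$chirality),
                one_hot(g$hybridizations, .vocab$hybridization))
  edge <- one_hot(g$bonds[, 3], .vocab$bond)
  list(node = node, edge = edge)
}

#' Message-passing graph embedding of each atom
#'
#' Three rounds of communicative node/edge message passing with fixed,
#' seed-determined weights: directed edge states are updated from the source
#' node state and the reverse edge, node states from max- and sum-pooled
#' incoming edge states.  The receptive field after three rounds is exactly
#' three bonds, matching the neighborhood of the local structure features.
#' The embedding depends only on the 2D graph, so for a fixed molecule it is
#' a constant per-node conditioning vector.
#'
#' @param g molecular_graph.
#' @param width embedding width (default 64).
#' @param n_layers message-passing rounds (default 3).
#' @param seed seed for the fixed weights.
#' @return N x width matrix of node embeddings.
#' @export
embed_graph <- function(g, width = 64L, n_layers = 3L, seed = 7L) {
  f <- featurize(g)
  n <- g$n_atoms
  b <- g$bonds
  # directed edges: (src, dst) both ways
  src <- c(b[, 1], b[, 2]); dst <- c(b[, 2], b[, 1])
  ne <- length(src)
  rev_idx <- c(seq_len(nrow(b)) + nrow(b), seq_len(nrow(b)))
  wts <- local_seed(seed, list(
    wn = matrix(stats::rnorm(ncol(f$node) * width, 0, 1 / sqrt(ncol(f$node))),
                ncol(f$node), width),
    we = matrix(stats::rnorm(ncol(f$edge) * width, 0, 1 / sqrt(ncol(f$edge))),
                ncol(f$edge), width),
    w_edge = lapply(seq_len(n_layers), function(l)
      matrix(stats::rnorm(2 * width * width, 0, 1 / sqrt(2 * width)),
             2 * width, width)),
    w_node = lapply(seq_len(n_layers), function(l)
      matrix(stats::rnorm(3 * width * width, 0, 1 / sqrt(3 * width)),
             3 * width, width))
  ))
  h <- tanh(f$node %*% wts$wn)                    # N x width
  e <- tanh(f$edge %*% wts$we)[rep(seq_len(nrow(b)), 2L), , drop = FALSE]
  for (l in seq_len(n_layers)) {
    # edge update: source node + reverse edge state
    e_new <- tanh(cbind(h[src, , drop = FALSE],
                        e[rev_idx, , drop = FALSE]) %*% wts$w_edge[[l]])
    # node update: sum- and max-pooled incoming edge states + self
    agg_sum <- matrix(0, n, width)
    agg_max <- matrix(-Inf, n, width)
    for (k in seq_len(ne)) {
      agg_sum[dst[k], ] <- agg_sum[dst[k], ] + e_new[k, ]
      agg_max[dst[k], ] <- pmax(agg_max[dst[k], ], e_new[k, ])
    }
    agg_max[!is.finite(agg_max)] <- 0
    h <- tanh(cbind(h, agg_sum, agg_max) %*% wts$w_node[[l]])
    e <- e_new
  }
  h
}

#' Training configuration for the autoencoders
#'
#' Defaults follow the reference settings: 128-dimensional latent space,
#' 5 percent multiplicative Gaussian noise on the latent code during
#' training, Tanh activations, Adam with a halving-on-plateau learning rate
#' that stops below 1e-8, and an early-stopping patience.
#'
#' @param latent_dim latent width per node (graph model) or per molecule
#'   (naive model).
#' @param hidden dense layer width of encoder/decoder (3 layers each).
#' @param cmpnn_width graph-embedding width.
#' @param noise_percent training-time latent noise fraction.
#' @param lr,lr_patience,lr_floor,early_stop,max_epochs,batch_size,val_fraction
#'   optimizer schedule.
#' @param seed master seed for split, init and noise.
#' @return list of class \code{gierc_train_config}.
#' @export
gierc_train_config <- function(latent_dim = 128L, hidden = 256L,
                               cmpnn_width = 64L, noise_percent = 0.05,
                               lr = 1e-3, lr_patience = 10L, lr_floor = 1e-8,
                               early_stop = 30L, max_epochs = 200L,
                               batch_size = 2048L, val_fraction = 0.1,
                               seed = 1L) {
  stopifnot(latent_dim > 0, hidden > 0, noise_percent >= 0, lr > 0)
  structure(list(latent_dim = latent_dim, hidden = hidden,
                 cmpnn_width = cmpnn_width, noise_percent = noise_percent,
                 lr = lr, lr_patience = lr_patience, lr_floor = lr_floor,
                 early_stop = early_stop, max_epochs = max_epochs,
                 batch_size = batch_size, val_fraction = val_fraction,
                 seed = seed), class = "gierc_train_config")
}

# stack encodings of an ensemble into per-node sample rows; returns
# list(x = (n_conf*N) x (m*3), mask row per node, encodings, ctx)
stack_node_features <- function(confs, g, ctx = NULL, m = NULL) {
  if (is.null(ctx)) ctx <- gierc_context(g)
  if (is.null(m)) m <- ctx$m_min
  n <- g$n_atoms
  encs <- lapply(confs, gierc_encode, m = m, ctx = ctx)
  x <- do.call(rbind, lapply(encs, function(f)
    matrix(f$features, n, m * 3L)))
  node_mask <- matrix(0, n, m * 3L)
  for (t in seq_len(n)) {
    mi <- ctx$m_i[ctx$s$order[t]]
    node_mask[t, c(seq_len(mi), m + seq_len(mi), 2L * m + seq_len(mi))] <- 1
  }
  list(x = x, node_mask = node_mask, encs = encs, ctx = ctx, m = m)
}

#' Train the graph-conditioned autoencoder
#'
#' Encodes every conformer to per-node local structure features, conditions
#' the decoder on fixed message-passing graph embeddings, and fits the
#' encoder/decoder MLPs (three dense layers each) with masked MSE: padding
#' rows never contribute to the loss.  The 9:1 train/validation split, all
#' initializations and the latent noise derive from the config seed; the
#' returned model holds the parameters of the best validation epoch.
#'
#' @param confs list of conformers (>= 100 recommended).
#' @param g molecular_graph.
#' @param cfg \code{\link{gierc_train_config}}.
#' @param ctx optional precomputed codec context.
#' @param verbose print per-epoch losses.
#' @return object of class \code{graph_ae}.
#' @export
graph_ae_train <- function(confs, g, cfg = gierc_train_config(),
                           ctx = NULL, verbose = FALSE) {
  sf <- stack_node_features(confs, g, ctx)
  ctx <- sf$ctx
  n <- g$n_atoms
  h <- embed_graph(g, cfg$cmpnn_width, seed = cfg$seed + 1L)
  h_canon <- h[ctx$s$order, , drop = FALSE]          # rows in slab order
  cond <- h_canon[rep(seq_len(n), length(confs)), , drop = FALSE]
  mask <- sf$node_mask[rep(seq_len(n), length(confs)), , drop = FALSE]
  d_in <- ncol(sf$x)
  fit <- ae_fit(sf$x, cond = cond, mask = mask,
                enc_sizes = c(d_in, cfg$hidden, cfg$hidden, cfg$hidden,
                              cfg$latent_dim),
                dec_sizes = c(cfg$cmpnn_width + cfg$latent_dim, cfg$hidden,
                              cfg$hidden, cfg$hidden, d_in),
                noise_percent = cfg$noise_percent, lr = cfg$lr,
                lr_patience = cfg$lr_patience, lr_floor = cfg$lr_floor,
                early_stop = cfg$early_stop, max_epochs = cfg$max_epochs,
                batch_size = cfg$batch_size, val_fraction = cfg$val_fraction,
                seed = cfg$seed, verbose = verbose)
  structure(list(variant = "graph_ae", enc = fit$enc, dec = fit$dec,
                 h_canon = h_canon, cfg = cfg, m = sf$m,
                 node_mask = sf$node_mask, fingerprint = ctx$fingerprint,
                 val_loss = fit$val_loss, log = fit$log),
            class = "graph_ae")
}

#' @export
print.graph_ae <- function(x, ...) {
  cat(sprintf("%s model: latent %d, best val MSE %.3e (epoch %d)\n",
              x$variant, x$cfg$latent_dim, x$val_loss,
              x$log$epoch[which.min(x$log$val)]))
  invisible(x)
}

# per-node latent codes of one conformer (inference: no noise)
graph_ae_encode_latent <- function(model, f) {
  n <- dim(f$features)[1]
  x <- matrix(f$features, n, model$m * 3L)
  mlp_forward(model$enc, x)
}

graph_ae_decode_latent <- function(model, z) {
  out <- mlp_forward(model$dec, cbind(model$h_canon, z))
  out * model$node_mask                               # zero the padding
}

#' Reconstruct a conformer through the graph autoencoder
#'
#' Encode to per-node latents, decode conditioned on the graph embedding,
#' then invert the GIE-RC encoding back to Cartesian coordinates.
#'
#' @param model graph_ae.
#' @param conf conformer.
#' @param ctx codec context of the molecule.
#' @return list(conformer, features): the rebuilt structure and the raw
#'   reconstructed feature tensor.
#' @export
graph_ae_reconstruct <- function(model, conf, ctx) {
  if (!identical(model$fingerprint, ctx$fingerprint))
    stop("model was trained on a different molecular graph")
  f <- gierc_encode(conf, m = model$m, ctx = ctx)
  z <- graph_ae_encode_latent(model, f)
  out <- graph_ae_decode_latent(model, z)
  f2 <- f
  f2$features <- array(out, dim(f$features))
  list(conformer = gierc_decode(f2, ctx = ctx), features = f2)
}

#' Linear latent-space interpolation between two conformers
#'
#' Encodes both endpoints to per-node latent codes and decodes equally
#' spaced convex combinations; the graph embedding (identical at both
#' endpoints) conditions every step.  Endpoints t = 0, 1 are exactly the
#' model's direct reconstructions.  Interior decode failures are flagged and
#' skipped, not fatal.
#'
#' @param model graph_ae.
#' @param conf_a,conf_b endpoint conformers.
#' @param ctx codec context.
#' @param steps number of intervals (default 20: 21 structures inclusive).
#' @return list(conformers, t, failed) where failed marks non-decodable
#'   interior steps (their conformer slot is NULL).
#' @export
interpolate_conformers <- function(model, conf_a, conf_b, ctx, steps = 20L) {
  fa <- gierc_encode(conf_a, m = model$m, ctx = ctx)
  fb <- gierc_encode(conf_b, m = model$m, ctx = ctx)
  za <- graph_ae_encode_latent(model, fa)
  zb <- graph_ae_encode_latent(model, fb)
  ts <- seq(0, 1, length.out = steps + 1L)
  confs <- vector("list", length(ts))
  failed <- logical(length(ts))
  for (k in seq_along(ts)) {
    z <- (1 - ts[k]) * za + ts[k] * zb
    out <- graph_ae_decode_latent(model, z)
    fk <- fa
    fk$features <- array(out, dim(fa$features))
    confs[[k]] <- tryCatch(gierc_decode(fk, ctx = ctx),
                           error = function(e) { failed[k] <<- TRUE; NULL })
  }
  list(conformers = confs, t = ts, failed = failed)
}

#' Train the naive (graph-free) autoencoder baseline
#'
#' Compresses the whole flattened feature tensor of each conformer through a
#' single global 128-dimensional latent code, with no graph conditioning:
#' the comparison arm for the graph model.
#'
#' @param confs list of conformers.
#' @param g molecular_graph.
#' @param cfg \code{\link{gierc_train_config}} (hidden is the widest dense
#'   layer; the encoder is hidden/2-wide at its second layer).
#' @param ctx optional codec context.
#' @param verbose print per-epoch losses.
#' @return object of class \code{naive_ae}.
#' @export
naive_ae_train <- function(confs, g, cfg = gierc_train_config(),
                           ctx = NULL, verbose = FALSE) {
  sf <- stack_node_features(confs, g, ctx)
  ctx <- sf$ctx
  n <- g$n_atoms
  x <- do.call(rbind, lapply(sf$encs, function(f) as.numeric(f$features)))
  # flatten the per-node masks in tensor (atom, row, xyz) order so they line
  # up with as.numeric(features)
  mask_arr <- array(0, c(n, sf$m, 3L))
  for (t in seq_len(n)) mask_arr[t, , ] <- matrix(sf$node_mask[t, ], sf$m, 3L)
  mask <- matrix(as.numeric(mask_arr), 1L)
  d_in <- ncol(x)
  fit <- ae_fit(x, cond = NULL, mask = mask,
                enc_sizes = c(d_in, cfg$hidden, cfg$hidden %/% 2L,
                              cfg$latent_dim),
                dec_sizes = c(cfg$latent_dim, cfg$hidden %/% 2L, cfg$hidden,
                              d_in),
                noise_percent = cfg$noise_percent, lr = cfg$lr,
                lr_patience = cfg$lr_patience, lr_floor = cfg$lr_floor,
                early_stop = cfg$early_stop, max_epochs = cfg$max_epochs,
                batch_size = min(cfg$batch_size, 256L),
                val_fraction = cfg$val_fraction,
                seed = cfg$seed, verbose = verbose)
  structure(list(variant = "naive_ae", enc = fit$enc, dec = fit$dec,
                 cfg = cfg, m = sf$m, mask = mask, dims = c(n, sf$m, 3L),
                 fingerprint = ctx$fingerprint, val_loss = fit$val_loss,
                 log = fit$log),
            class = c("naive_ae", "graph_ae"))
}

#' Reconstruct a conformer through the naive autoencoder
#'
#' @param model naive_ae.
#' @param conf conformer.
#' @param ctx codec context.
#' @return list(conformer, features).
#' @export
naive_ae_reconstruct <- function(model, conf, ctx) {
  if (!identical(model$fingerprint, ctx$fingerprint))
    stop("model was trained on a different molecular graph")
  f <- gierc_encode(conf, m = model$m, ctx = ctx)
  x <- matrix(as.numeric(f$features), 1L)
  out <- mlp_forward(model$dec, mlp_forward(model$enc, x)) * model$mask
  f2 <- f
  f2$features <- array(out, model$dims)
  list(conformer = gierc_decode(f2, ctx = ctx), features = f2)
}

#' Cluster conformers in torsion space
#'
#' DBSCAN over the canonical torsion vectors with a circular Euclidean
#' metric; clusters smaller than \code{min_cluster_size} are relabeled as
#' noise (label 0).
#'
#' @param confs list of conformers (>= 2).
#' @param g molecular_graph.
#' @param eps DBSCAN radius, degrees (in the wrapped-difference metric).
#' @param min_cluster_size smallest cluster kept.
#' @param min_samples DBSCAN core-point threshold (neighbors within eps,
#'   self included).
#' @return integer cluster labels, 0 = noise.
#' @export
cluster_conformers <- function(confs, g, eps = 30, min_cluster_size = 1L,
                               min_samples = 5L) {
  if (length(confs) < 2L) stop("need at least 2 conformers")
  quads <- canonical_torsions(g)
  tmat <- do.call(rbind, lapply(confs, conformer_torsions, quads = quads))
  n <- nrow(tmat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    dd <- sqrt(colSums(wrap_angle(t(tmat[(i + 1L):n, , drop = FALSE]) -
                                  tmat[i, ])^2))
    d[i, (i + 1L):n] <- dd; d[(i + 1L):n, i] <- dd
  }
  labels <- dbscan_matrix(d, eps, min_samples)
  for (l in setdiff(unique(labels), 0L))
    if (sum(labels == l) < min_cluster_size) labels[labels == l] <- 0L
  match(labels, c(0L, setdiff(unique(labels[order(labels)]), 0L))) - 1L
}
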