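#' Generator architecture specification
#'
#' The generator is a fully connected network that maps the concatenation
#' of (scaled source profile, source condition label, target condition
#' label, noise block) to a sigmoid-activated synthetic profile for the
#' target organ. Defaults mirror the full-scale architecture: five hidden
#' layers of 8192/7168/7168/4096/4096 leaky-ReLU units (alpha 0.2) with
#' dropout 0.8/0.8/0.8/0.4 after all hidden layers but the last. At the
#' full scale (3475 genes, 14-bit labels, 3475-dimensional noise) the input
#' width is 3475 + 14 + 14 + 3475 = 6978.
#'
#' @param gene_dim Number of genes (input profile and output width).
#' @param label_width Width of each condition label block.
#' @param noise_dim Width of the noise block (default: `gene_dim`; 0 is
#'   allowed for ablation).
#' @param hidden Hidden-layer widths.
#' @param dropout_rates Dropout rate after each hidden layer except the
#'   last; length must be `length(hidden) - 1`.
#' @param leaky_relu_alpha Negative-slope coefficient of the hidden
#'   activations.
#' @return A `generator_spec` object with an `input_width` field.
#' @export
generator_spec <- function(gene_dim, label_width = 14L,
                           noise_dim = gene_dim,
                           hidden = c(8192L, 7168L, 7168L, 4096L, 4096L),
                           dropout_rates = c(0.8, 0.8, 0.8, 0.4),
                           leaky_relu_alpha = 0.2) {
  stopifnot(gene_dim >= 1, label_width >= 1, noise_dim >= 0,
            length(hidden) >= 1)
  if (length(dropout_rates) != length(hidden) - 1L)
    stop("dropout_rates must have length(hidden) - 1 entries", call. = FALSE)
  if (any(dropout_rates < 0 | dropout_rates >= 1))
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  structure(list(gene_dim = as.integer(gene_dim),
                 label_width = as.integer(label_width),
                 noise_dim = as.integer(noise_dim),
                 input_width = as.integer(gene_dim + 2L * label_width + noise_dim),
                 hidden = as.integer(hidden),
                 dropout_rates = dropout_rates,
                 leaky_relu_alpha = leaky_relu_alpha),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' A fully connected real-vs-synthetic classifier over a single (scaled)
#' profile: defaults are two hidden layers of 256 and 64 ReLU units each
#' followed by dropout 0.5, and one sigmoid output unit. Trained with
#' stochastic gradient descent (learning rate 1e-4, momentum 0.90).
#'
#' @param gene_dim Number of genes (input width).
#' @param hidden Hidden-layer widths.
#' @param dropout_rate Dropout rate applied after each hidden layer
#'   (scalar, recycled).
#' @return A `discriminator_spec` object.
#' @export
discriminator_spec <- function(gene_dim, hidden = c(256L, 64L),
                               dropout_rate = 0.5) {
  stopifnot(gene_dim >= 1, length(hidden) >= 1,
            all(dropout_rate >= 0 & dropout_rate < 1))
  structure(list(gene_dim = as.integer(gene_dim),
                 hidden = as.integer(hidden),
                 dropout_rate = rep_len(dropout_rate, length(hidden))),
            class = "discriminator_spec")
}

#' Training configuration for the organ translator
#'
#' @param epochs Number of passes over the pair list.
#' @param batch_size Pairs per update step.
#' @param lambda_cycle Weight of the cycle-consistency (L1 back-translation)
#'   loss relative to the adversarial loss.
#' @param g_lr,g_beta1,g_beta2 Adam settings for the generators.
#' @param d_lr,d_momentum SGD-momentum settings for the discriminators.
#' @param noise_dim Noise-block width; `NULL` means "equal to gene_dim".
#' @param gen_hidden,gen_dropout,disc_hidden,disc_dropout Architecture
#'   overrides passed to [generator_spec()] / [discriminator_spec()].
#' @param leaky_alpha Leaky-ReLU slope for the generators.
#' @param val_fraction Fraction of pairs held out to track validation
#'   cosine (the best-validation weights are kept alongside the final
#'   ones; `selection` picks which one [translate_profiles()] uses).
#' @param eval_every Epoch cadence of the validation pass.
#' @param selection `"final"` (fixed epoch budget, default) or `"best"`
#'   (best validation cosine checkpoint).
#' @param seed Master seed for init, shuffling, dropout and noise.
#' @param verbose Print per-epoch losses.
#' @return A `transtox_config` list.
#' @export
transtox_config <- function(epochs = 1000L, batch_size = 128L,
                            lambda_cycle = 10, g_lr = 1e-4, g_beta1 = 0.5,
                            g_beta2 = 0.999, d_lr = 1e-4, d_momentum = 0.9,
                            noise_dim = NULL,
                            gen_hidden = c(8192L, 7168L, 7168L, 4096L, 4096L),
                            gen_dropout = c(0.8, 0.8, 0.8, 0.4),
                            disc_hidden = c(256L, 64L), disc_dropout = 0.5,
                            leaky_alpha = 0.2, val_fraction = 0.05,
                            eval_every = 25L,
                            selection = c("final", "best"),
                            seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lambda_cycle >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lambda_cycle = lambda_cycle, g_lr = g_lr,
                 g_beta1 = g_beta1, g_beta2 = g_beta2, d_lr = d_lr,
                 d_momentum = d_momentum, noise_dim = noise_dim,
                 gen_hidden = as.integer(gen_hidden),
                 gen_dropout = gen_dropout,
                 disc_hidden = as.integer(disc_hidden),
                 disc_dropout = disc_dropout, leaky_alpha = leaky_alpha,
                 val_fraction = val_fraction,
                 eval_every = as.integer(eval_every),
                 selection = match.arg(selection),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "transtox_config")
}

#' Draw a noise block in \[0, 1\]
#'
#' Standard-normal draws clipped to \[-3, 3\] and affinely mapped onto
#' \[0, 1\], so the noise respects the generator input's bounded range
#' while keeping a near-Gaussian shape. The mapped values are symmetric
#' about 0.5.
#'
#' @param noise_dim Noise width (0 gives an empty block).
#' @param n Number of rows (draws).
#' @param seed Optional seed; if `NULL`, draws from the current RNG stream.
#' @return An `n x noise_dim` matrix in \[0, 1\].
#' @export
sample_noise <- function(noise_dim, n, seed = NULL) {
  stopifnot(n >= 1, noise_dim >= 0)
  draw <- function() {
    z <- matrix(stats::rnorm(n * noise_dim), n, noise_dim)
    (pmin(pmax(z, -3), 3) + 3) / 6
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Assemble a generator input vector
#'
#' Fixed component order: scaled profile, source label, target label,
#' noise. All components must already be in \[0, 1\].
#'
#' @param profile_scaled Numeric vector (one profile, scaled) or matrix
#'   (rows = profiles).
#' @param source_label,target_label Binary label vector(s) from
#'   [encode_label()].
#' @param noise Noise vector/matrix from [sample_noise()] (may have zero
#'   columns).
#' @return A matrix with `gene_dim + 2 * label_width + noise_dim` columns.
#' @export
assemble_generator_input <- function(profile_scaled, source_label,
                                     target_label, noise) {
  as_row <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  profile_scaled <- as_row(profile_scaled)
  source_label <- as_row(source_label)
  target_label <- as_row(target_label)
  noise <- if (is.null(noise) || length(noise) == 0L)
    matrix(0, nrow(profile_scaled), 0L) else as_row(noise)
  n <- nrow(profile_scaled)
  for (comp in c("source_label", "target_label", "noise")) {
    m <- get(comp)
    if (nrow(m) != n)
      stop("component '", comp, "' has ", nrow(m), " rows, expected ", n,
           call. = FALSE)
  }
  if (ncol(source_label) != ncol(target_label))
    stop("component 'target_label' width differs from 'source_label'",
         call. = FALSE)
  out <- cbind(profile_scaled, source_label, target_label, noise,
               deparse.level = 0)
  if (any(out < 0 | out > 1))
    stop("generator input components must lie in [0, 1]", call. = FALSE)
  unname(out)
}

#' Mean binary cross-entropy from predicted probabilities
#' @param p Predicted probabilities in (0, 1).
#' @param target 0/1 targets.
#' @keywords internal
#' @export
binary_cross_entropy <- function(p, target) {
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# --- internal helpers shared by training / diagnostics -----------------

build_label_matrix <- function(meta, schema) {
  encode_label(meta$organ, meta$dose, meta$time_days, schema)
}

resolve_batch <- function(model_env, src_ids, tgt_ids) {
  list(Xs = model_env$X[src_ids, , drop = FALSE],
       Xt = model_env$X[tgt_ids, , drop = FALSE],
       Ls = model_env$labels[src_ids, , drop = FALSE],
       Lt = model_env$labels[tgt_ids, , drop = FALSE])
}

#' Loss components of the translator on a batch of pairs
#'
#' Computes (without updating any weights) the discriminator losses (BCE,
#' real profiles toward 1, generated toward 0), the generator adversarial
#' loss (BCE of the discriminator on generated profiles toward 1), the L1
#' cycle-consistency loss between each source profile and its
#' back-translation, and the combined generator objective
#' `g_adv + lambda_cycle * cycle`.
#'
#' @param model A fitted or freshly initialised `transtox_fit`.
#' @param pairs Pair tibble from [build_pairs()] (any subset of rows).
#' @param expression Combined genes x samples log2 matrix covering all
#'   referenced samples.
#' @param metadata Sample metadata tibble.
#' @param lambda_cycle Cycle weight; defaults to the model's training value.
#' @return A one-row tibble with columns `d_liver_loss`, `d_kidney_loss`,
#'   `g_adv_loss`, `cycle_loss`, `total_g_loss`.
#' @export
gan_losses <- function(model, pairs, expression, metadata,
                       lambda_cycle = NULL) {
  stopifnot(inherits(model, "transtox_fit"))
  lambda_cycle <- lambda_cycle %||% model$config$lambda_cycle
  env <- model_tensors(model, expression, metadata)
  acc <- list(d_liver = c(), d_kidney = c(), g_adv = c(), cycle = c())
  for (dir in intersect(c("to_liver", "to_kidney"), unique(pairs$direction))) {
    rows <- pairs[pairs$direction == dir, ]
    b <- resolve_batch(env, rows$source_sample_id, rows$target_sample_id)
    G_fwd <- model$nets[[paste0("G_", sub("to_", "", dir))]]
    G_back <- model$nets[[paste0("G_", ifelse(dir == "to_liver", "kidney", "liver"))]]
    D <- model$nets[[paste0("D_", sub("to_", "", dir))]]
    nd <- model$noise_dim
    z1 <- sample_noise(nd, nrow(b$Xs))
    z2 <- sample_noise(nd, nrow(b$Xs))
    fake <- mlp_forward(G_fwd, cbind(b$Xs, b$Ls, b$Lt, z1))$out
    back <- mlp_forward(G_back, cbind(fake, b$Lt, b$Ls, z2))$out
    p_real <- mlp_forward(D, b$Xt)$out
    p_fake <- mlp_forward(D, fake)$out
    d_loss <- binary_cross_entropy(c(p_real, p_fake),
                                   c(rep(1, length(p_real)), rep(0, length(p_fake))))
    organ <- sub("to_", "", dir)
    acc[[paste0("d_", organ)]] <- c(acc[[paste0("d_", organ)]], d_loss)
    acc$g_adv <- c(acc$g_adv, binary_cross_entropy(p_fake, rep(1, length(p_fake))))
    acc$cycle <- c(acc$cycle, mean(abs(back - b$Xs)))
  }
  m <- function(x) if (length(x)) mean(x) else NA_real_
  g_adv <- m(acc$g_adv)
  cyc <- m(acc$cycle)
  out <- tibble::tibble(d_liver_loss = m(acc$d_liver),
                        d_kidney_loss = m(acc$d_kidney),
                        g_adv_loss = g_adv, cycle_loss = cyc,
                        total_g_loss = g_adv + lambda_cycle * cyc)
  vals <- unlist(out)
  if (any(!is.finite(vals[!is.na(vals)])))
    stop("non-finite GAN loss encountered", call. = FALSE)
  out
}

model_tensors <- function(model, expression, metadata) {
  meta <- metadata[match(colnames(expression), metadata$sample_id), ]
  if (anyNA(meta$sample_id))
    stop("expression columns missing from metadata", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$X <- t(apply_scaler(model$scaler, expression))
  env$labels <- build_label_matrix(meta, model$schema)
  rownames(env$labels) <- meta$sample_id
  env
}

init_transtox <- function(gene_ids, config, schema) {
  gene_dim <- length(gene_ids)
  noise_dim <- config$noise_dim %||% gene_dim
  gspec <- generator_spec(gene_dim, schema$label_width, noise_dim,
                          hidden = config$gen_hidden,
                          dropout_rates = config$gen_dropout,
                          leaky_relu_alpha = config$leaky_alpha)
  g_sizes <- c(gspec$input_width, gspec$hidden, gene_dim)
  g_drop <- c(gspec$dropout_rates, 0)
  d_sizes <- c(gene_dim, config$disc_hidden, 1L)
  d_drop <- rep_len(config$disc_dropout, length(config$disc_hidden))
  nets <- list(
    G_liver = mlp_init(g_sizes, alpha = config$leaky_alpha, dropout = g_drop),
    G_kidney = mlp_init(g_sizes, alpha = config$leaky_alpha, dropout = g_drop),
    D_liver = mlp_init(d_sizes, alpha = 0, dropout = d_drop),
    D_kidney = mlp_init(d_sizes, alpha = 0, dropout = d_drop)
  )
  list(nets = nets, gspec = gspec, noise_dim = noise_dim)
}

#' Train the cross-organ translator
#'
#' Alternating adversarial training on drug-specific pairwise samples: per
#' batch and per direction, one discriminator step (BCE, real target
#' profiles vs generated ones) followed by one generator step minimising
#' the adversarial loss plus `lambda_cycle` times the L1 cycle loss
#' (source profile vs its round-trip back-translation through both
#' generators). The feature scaler is fitted on the training samples'
#' expression only. All randomness (weight init, shuffling, dropout,
#' noise, validation holdout) derives from `config$seed`.
#'
#' @param pairs Pair tibble from [build_pairs()] (training compounds only).
#' @param expression Genes x samples log2 matrix covering every sample
#'   referenced by `pairs`.
#' @param metadata Sample metadata tibble.
#' @param config A [transtox_config()].
#' @param schema Label schema shared by training and translation.
#' @return A `transtox_fit` object: the four networks, scaler, schema,
#'   config, and a per-epoch loss history (`tidy()` it, or `autoplot()`).
#' @export
train_transtox <- function(pairs, expression, metadata,
                           config = transtox_config(),
                           schema = label_schema()) {
  stopifnot(inherits(config, "transtox_config"))
  if (nrow(pairs) == 0L) stop("empty pair list", call. = FALSE)
  used <- unique(c(pairs$source_sample_id, pairs$target_sample_id))
  missing <- setdiff(used, colnames(expression))
  if (length(missing))
    stop("expression matrix missing paired sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  with_seed(config$seed, {
    scaler <- fit_scaler(expression[, used, drop = FALSE])
    init <- init_transtox(rownames(expression), config, schema)
    model <- structure(list(nets = init$nets, scaler = scaler,
                            schema = schema, config = config,
                            noise_dim = init$noise_dim,
                            gene_ids = rownames(expression),
                            loss_history = NULL, epochs_run = 0L),
                       class = "transtox_fit")
    env <- model_tensors(model, expression[, used, drop = FALSE],
                         metadata)

    # validation holdout for checkpoint tracking
    n_val <- floor(config$val_fraction * nrow(pairs))
    val_idx <- if (n_val >= 2L) sample(nrow(pairs), n_val) else integer(0)
    train_pairs <- if (length(val_idx)) pairs[-val_idx, ] else pairs
    val_pairs <- pairs[val_idx, ]

    opt <- list(
      G_liver = opt_init(model$nets$G_liver, "adam", lr = config$g_lr,
                         beta1 = config$g_beta1, beta2 = config$g_beta2),
      G_kidney = opt_init(model$nets$G_kidney, "adam", lr = config$g_lr,
                          beta1 = config$g_beta1, beta2 = config$g_beta2),
      D_liver = opt_init(model$nets$D_liver, "sgd", lr = config$d_lr,
                         momentum = config$d_momentum),
      D_kidney = opt_init(model$nets$D_kidney, "sgd", lr = config$d_lr,
                          momentum = config$d_momentum)
    )

    history <- vector("list", config$epochs)
    best <- list(cosine = -Inf, nets = NULL, epoch = NA_integer_)
    nd <- model$noise_dim
    lam <- config$lambda_cycle

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(nrow(train_pairs))
      ep <- list(d_liver = c(), d_kidney = c(), g_adv = c(), cycle = c())
      for (start in seq(1L, nrow(train_pairs), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(train_pairs))]
        bp <- train_pairs[idx, ]
        for (dir in intersect(c("to_liver", "to_kidney"), unique(bp$direction))) {
          rows <- bp[bp$direction == dir, ]
          organ <- sub("to_", "", dir)
          other <- ifelse(organ == "liver", "kidney", "liver")
          b <- resolve_batch(env, rows$source_sample_id, rows$target_sample_id)
          n <- nrow(b$Xs)
          Gf_name <- paste0("G_", organ)
          Gb_name <- paste0("G_", other)
          D_name <- paste0("D_", organ)

          z1 <- sample_noise(nd, n)
          fwd_g <- mlp_forward(model$nets[[Gf_name]],
                               cbind(b$Xs, b$Ls, b$Lt, z1), train = TRUE)
          fake <- fwd_g$out

          # --- discriminator step (fake detached) ---
          Din <- rbind(b$Xt, fake)
          dt <- c(rep(1, n), rep(0, n))
          fwd_d <- mlp_forward(model$nets[[D_name]], Din, train = TRUE)
          bce_d <- bce_from_logits(fwd_d$logits, dt)
          gr_d <- mlp_backward(model$nets[[D_name]], fwd_d, bce_d$grad)
          stp <- opt_step(model$nets[[D_name]], gr_d, opt[[D_name]])
          model$nets[[D_name]] <- stp$net
          opt[[D_name]] <- stp$state
          ep[[paste0("d_", organ)]] <- c(ep[[paste0("d_", organ)]], bce_d$loss)

          # --- generator step: adversarial + cycle ---
          fwd_d2 <- mlp_forward(model$nets[[D_name]], fake)
          bce_g <- bce_from_logits(fwd_d2$logits, rep(1, n))
          gr_adv <- mlp_backward(model$nets[[D_name]], fwd_d2, bce_g$grad)
          d_fake_adv <- gr_adv$dX

          z2 <- sample_noise(nd, n)
          fwd_b <- mlp_forward(model$nets[[Gb_name]],
                               cbind(fake, b$Lt, b$Ls, z2), train = TRUE)
          back <- fwd_b$out
          cyc_loss <- mean(abs(back - b$Xs))
          d_back <- lam * sign(back - b$Xs) / length(back)
          gr_back <- mlp_backward(model$nets[[Gb_name]], fwd_b, d_back,
                                  from_logits = FALSE)
          gdim <- length(model$gene_ids)
          d_fake_cycle <- gr_back$dX[, seq_len(gdim), drop = FALSE]

          gr_fwd <- mlp_backward(model$nets[[Gf_name]], fwd_g,
                                 d_fake_adv + d_fake_cycle,
                                 from_logits = FALSE)
          if (any(!vapply(gr_fwd$dW, function(m) all(is.finite(m)), TRUE)))
            stop("non-finite generator gradient at epoch ", epoch, call. = FALSE)
          stp <- opt_step(model$nets[[Gf_name]], gr_fwd, opt[[Gf_name]])
          model$nets[[Gf_name]] <- stp$net
          opt[[Gf_name]] <- stp$state
          stp <- opt_step(model$nets[[Gb_name]], gr_back, opt[[Gb_name]])
          model$nets[[Gb_name]] <- stp$net
          opt[[Gb_name]] <- stp$state

          ep$g_adv <- c(ep$g_adv, bce_g$loss)
          ep$cycle <- c(ep$cycle, cyc_loss)
        }
      }
      m <- function(x) if (length(x)) mean(x) else NA_real_
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, d_liver = m(ep$d_liver), d_kidney = m(ep$d_kidney),
        g_adv = m(ep$g_adv), cycle = m(ep$cycle),
        total_g = m(ep$g_adv) + lam * m(ep$cycle))
      vals <- unlist(history[[epoch]][-1])
      if (any(!is.finite(vals[!is.na(vals)])))
        stop("non-finite loss at epoch ", epoch, call. = FALSE)
      if (length(val_idx) &&
          (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
        vc <- validation_cosine(model, env, val_pairs)
        if (vc > best$cosine)
          best <- list(cosine = vc, nets = model$nets, epoch = epoch)
      }
      if (config$verbose)
        message(sprintf("epoch %d: D(l)=%.4f D(k)=%.4f adv=%.4f cyc=%.5f",
                        epoch, history[[epoch]]$d_liver,
                        history[[epoch]]$d_kidney,
                        history[[epoch]]$g_adv, history[[epoch]]$cycle))
    }
    model$loss_history <- dplyr::bind_rows(history)
    model$epochs_run <- config$epochs
    model$best_val <- best[c("cosine", "epoch")]
    if (config$selection == "best" && !is.null(best$nets))
      model$nets <- best$nets
    model
  })
}

validation_cosine <- function(model, env, val_pairs) {
  vals <- numeric(0)
  for (dir in intersect(c("to_liver", "to_kidney"), unique(val_pairs$direction))) {
    rows <- val_pairs[val_pairs$direction == dir, ]
    b <- resolve_batch(env, rows$source_sample_id, rows$target_sample_id)
    G <- model$nets[[paste0("G_", sub("to_", "", dir))]]
    z <- sample_noise(model$noise_dim, nrow(b$Xs))
    fake <- mlp_forward(G, cbind(b$Xs, b$Ls, b$Lt, z))$out
    vals <- c(vals, vapply(seq_len(nrow(fake)), function(i)
      cosine_similarity(fake[i, ], b$Xt[i, ]), 0))
  }
  mean(vals)
}

#' @export
print.transtox_fit <- function(x, ...) {
  cat("<transtox_fit>", length(x$gene_ids), "genes,",
      x$epochs_run, "epochs trained\n")
  if (!is.null(x$loss_history) && nrow(x$loss_history)) {
    tail1 <- x$loss_history[nrow(x$loss_history), ]
    cat(sprintf("  final losses: D(liver)=%.4f D(kidney)=%.4f adv=%.4f cycle=%.5f\n",
                tail1$d_liver, tail1$d_kidney, tail1$g_adv, tail1$cycle))
  }
  invisible(x)
}

#' @rdname train_transtox
#' @param x A `transtox_fit`.
#' @param ... Unused.
#' @export
tidy.transtox_fit <- function(x, ...) {
  tidyr::pivot_longer(x$loss_history, -"epoch",
                      names_to = "loss", values_to = "value")
}

#' @rdname train_transtox
#' @export
glance.transtox_fit <- function(x, ...) {
  tail1 <- x$loss_history[nrow(x$loss_history), ]
  tibble::tibble(n_genes = length(x$gene_ids), epochs = x$epochs_run,
                 d_liver = tail1$d_liver, d_kidney = tail1$d_kidney,
                 g_adv = tail1$g_adv, cycle = tail1$cycle,
                 best_val_cosine = x$best_val$cosine %||% NA_real_)
}

#' Translate profiles to the other organ
#'
#' Runs the trained target-organ generator on each input profile for each
#' requested target condition and maps the sigmoid outputs back to log2
#' units through the training scaler, so outputs always lie inside the
#' per-gene training range (when the scaler clips). Dropout is disabled at
#' translation time; the noise block is drawn from `seed`, so the same
#' seed reproduces the synthetic matrix exactly.
#'
#' @param model A `transtox_fit`.
#' @param profiles Genes x samples log2 matrix of source-organ profiles.
#' @param source_meta Metadata rows for the profile columns (all one
#'   organ).
#' @param target_conditions Tibble with columns `organ`, `dose`,
#'   `time_days`; all rows must name the organ opposite the source. If
#'   `NULL`, each profile is translated to its own (dose, time) condition
#'   in the other organ.
#' @param seed Seed for the noise draws.
#' @return Genes x (n_profiles * n_conditions) matrix of synthetic log2
#'   profiles; the `"provenance"` attribute is a tibble recording source
#'   sample, target condition and seed per column.
#' @export
translate_profiles <- function(model, profiles, source_meta,
                               target_conditions = NULL, seed = 1L) {
  stopifnot(inherits(model, "transtox_fit"))
  source_meta <- source_meta[match(colnames(profiles), source_meta$sample_id), ]
  if (anyNA(source_meta$sample_id))
    stop("profiles contain samples absent from source_meta", call. = FALSE)
  src_organ <- unique(source_meta$organ)
  if (length(src_organ) != 1L)
    stop("source profiles must come from a single organ", call. = FALSE)
  tgt_organ <- setdiff(c("liver", "kidney"), src_organ)
  if (is.null(target_conditions)) {
    target_conditions <- tibble::tibble(organ = tgt_organ,
                                        dose = source_meta$dose,
                                        time_days = source_meta$time_days)
    per_profile <- TRUE
  } else {
    per_profile <- FALSE
    if (!all(target_conditions$organ == tgt_organ))
      stop("target_conditions organ must be '", tgt_organ,
           "' (opposite of the source organ)", call. = FALSE)
  }
  G <- model$nets[[paste0("G_", tgt_organ)]]
  Xs <- t(apply_scaler(model$scaler, profiles))
  Ls <- build_label_matrix(source_meta, model$schema)
  with_seed(seed, {
    if (per_profile) {
      Lt <- build_label_matrix(target_conditions, model$schema)
      z <- sample_noise(model$noise_dim, nrow(Xs))
      out_scaled <- mlp_forward(G, cbind(Xs, Ls, Lt, z))$out
      prov <- tibble::tibble(
        column = paste0(source_meta$sample_id, "..", tgt_organ),
        source_sample_id = source_meta$sample_id,
        compound = source_meta$compound,
        replicate_id = source_meta$replicate_id,
        target_organ = tgt_organ,
        target_dose = target_conditions$dose,
        target_time = target_conditions$time_days, seed = seed)
    } else {
      blocks <- vector("list", nrow(target_conditions))
      provs <- vector("list", nrow(target_conditions))
      for (i in seq_len(nrow(target_conditions))) {
        tc <- target_conditions[i, ]
        Lt <- matrix(rep(encode_label(tc$organ, tc$dose, tc$time_days,
                                      model$schema),
                         each = nrow(Xs)), nrow = nrow(Xs))
        z <- sample_noise(model$noise_dim, nrow(Xs))
        blocks[[i]] <- mlp_forward(G, cbind(Xs, Ls, Lt, z))$out
        provs[[i]] <- tibble::tibble(
          column = paste0(source_meta$sample_id, "..", tgt_organ, "_",
                          tc$dose, "_", tc$time_days, "d"),
          source_sample_id = source_meta$sample_id,
          compound = source_meta$compound,
          replicate_id = source_meta$replicate_id,
          target_organ = tgt_organ, target_dose = tc$dose,
          target_time = tc$time_days, seed = seed)
      }
      out_scaled <- do.call(rbind, blocks)
      prov <- dplyr::bind_rows(provs)
    }
    synth <- invert_scaler(model$scaler, t(out_scaled))
    colnames(synth) <- prov$column
    rownames(synth) <- model$gene_ids
    attr(synth, "provenance") <- prov
    synth
  })
}

#' Metadata view of a synthetic matrix
#'
#' Builds a sample-metadata tibble for the columns of a
#' [translate_profiles()] result from its provenance attribute, so
#' synthetic profiles drop into [condition_profiles()], [fold_changes()]
#' and the classifier machinery exactly like measured ones.
#'
#' @param synth A matrix returned by [translate_profiles()].
#' @return Metadata tibble (empty `findings`).
#' @export
synthetic_sample_metadata <- function(synth) {
  prov <- attr(synth, "provenance")
  if (is.null(prov)) stop("matrix carries no provenance attribute", call. = FALSE)
  tibble::tibble(sample_id = prov$column, compound = prov$compound,
                 organ = prov$target_organ, dose = prov$target_dose,
                 time_days = prov$target_time,
                 replicate_id = prov$replicate_id,
                 findings = rep(list(character(0)), nrow(prov)))
}
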