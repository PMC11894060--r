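# Pharmacophore-conditioned autoregressive SMILES decoder.
#
# A slim GPT-style causal transformer: the condition vector (fingerprint
# bits or clipped feature counts) is injected as a prefix of learned
# value+channel embeddings (segment label 0), followed by the begin token
# and the SMILES tokens (segment label 1). Rotary positional encoding is
# applied to queries and keys inside standard softmax causal attention;
# pre-layer-norm blocks; the head predicts the next SMILES token, and the
# cross-entropy loss is masked to SMILES prediction positions only.
#
# Forward and backward passes are written directly in R matrix algebra:
# sequences in a batch are concatenated row-wise, linear layers run as
# single matrix products, and attention loops over (sequence, head).

CONDITION_LENGTHS <- c(fingerprint_72 = 72L, fingerprint_108 = 108L,
                       fingerprint_1032 = 1032L, counts_8 = 8L, none = 0L)
COUNT_CLIP <- 15L

#' Decoder configuration
#'
#' @param n_layers,n_heads,embed_dim,feedforward_dim Transformer shape.
#'   `embed_dim` must be divisible by `2 * n_heads` so rotary encoding
#'   can pair dimensions within each head.
#' @param max_seq_len Maximum total sequence length (condition prefix +
#'   begin token + SMILES tokens).
#' @param rope_theta Rotary encoding base.
#' @param condition_kind One of `"fingerprint_72"`, `"fingerprint_108"`,
#'   `"fingerprint_1032"`, `"counts_8"`, `"none"`.
#' @param dropout Dropout rate in `[0, 1)` applied to block outputs
#'   during training.
#' @param seed Integer seed controlling initialisation and batch order.
#' @return A list of class `decoder_config`.
#' @examples
#' decoder_config(condition_kind = "none")
#' @export
decoder_config <- function(n_layers = 2L, n_heads = 4L, embed_dim = 64L,
                           feedforward_dim = 4L * embed_dim,
                           max_seq_len = 192L, rope_theta = 10000,
                           condition_kind = c("fingerprint_72",
                                              "fingerprint_108",
                                              "fingerprint_1032",
                                              "counts_8", "none"),
                           dropout = 0, seed = 1L) {
  condition_kind <- match.arg(condition_kind)
  stopifnot(n_layers >= 1, n_heads >= 1, embed_dim >= 2,
            feedforward_dim >= 1, max_seq_len >= 1, rope_theta > 0,
            dropout >= 0, dropout < 1)
  if (embed_dim %% (2L * n_heads) != 0L) {
    stop("embed_dim must be divisible by 2 * n_heads")
  }
  structure(list(
    n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
    embed_dim = as.integer(embed_dim),
    feedforward_dim = as.integer(feedforward_dim),
    max_seq_len = as.integer(max_seq_len), rope_theta = rope_theta,
    condition_kind = condition_kind, dropout = dropout,
    seed = as.integer(seed)), class = "decoder_config")
}

condition_length <- function(config) {
  unname(CONDITION_LENGTHS[config$condition_kind])
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_params <- function(config, vocab_size) {
  d <- config$embed_dim
  ff <- config$feedforward_dim
  cl <- condition_length(config)
  sd0 <- 0.02
  p <- list(
    tok_emb = rmat(vocab_size, d, sd0),
    seg_emb = rmat(2L, d, sd0),
    lnf_g = rep(1, d), lnf_b = rep(0, d),
    w_out = rmat(d, vocab_size, sd0), b_out = rep(0, vocab_size)
  )
  if (cl > 0L) {
    p$val_emb <- rmat(COUNT_CLIP + 1L, d, sd0)
    p$chan_emb <- rmat(cl, d, sd0)
  }
  for (l in seq_len(config$n_layers)) {
    p[[paste0("ln1_g", l)]] <- rep(1, d)
    p[[paste0("ln1_b", l)]] <- rep(0, d)
    p[[paste0("w_qkv", l)]] <- rmat(d, 3L * d, sd0)
    p[[paste0("b_qkv", l)]] <- rep(0, 3L * d)
    p[[paste0("w_o", l)]] <- rmat(d, d, sd0 / sqrt(2 * config$n_layers))
    p[[paste0("b_o", l)]] <- rep(0, d)
    p[[paste0("ln2_g", l)]] <- rep(1, d)
    p[[paste0("ln2_b", l)]] <- rep(0, d)
    p[[paste0("w_f1", l)]] <- rmat(d, ff, sd0)
    p[[paste0("b_f1", l)]] <- rep(0, ff)
    p[[paste0("w_f2", l)]] <- rmat(ff, d, sd0 / sqrt(2 * config$n_layers))
    p[[paste0("b_f2", l)]] <- rep(0, d)
  }
  p
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# upper-triangle index cache keyed by sequence length (causal mask)
.mask_cache <- new.env(parent = emptyenv())
causal_mask_idx <- function(l) {
  key <- as.character(l)
  m <- .mask_cache[[key]]
  if (is.null(m)) {
    m <- which(upper.tri(matrix(0, l, l)))
    .mask_cache[[key]] <- m
  }
  m
}

rowmax_masked <- function(s) s[cbind(seq_len(nrow(s)), max.col(s, "first"))]

ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, `*`)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

# Build the concatenated embedding matrix for a batch.
# batch: list of examples, each list(cond = integer vector (possibly
# empty), ids = input token ids (begin + SMILES tokens), targets =
# next-token ids aligned with the SMILES prediction positions).
embed_batch <- function(params, config, batch) {
  cl <- condition_length(config)
  lens <- vapply(batch, function(e) cl + length(e$ids), integer(1))
  offsets <- c(0L, cumsum(lens))
  n <- sum(lens)
  d <- config$embed_dim
  x <- matrix(0, n, d)
  pos <- integer(n)
  tok_rows <- integer(0)   # rows taking token embeddings
  tok_ids <- integer(0)
  val_rows <- integer(0); val_ids <- integer(0)
  chan_rows <- integer(0); chan_ids <- integer(0)
  seg <- integer(n)
  for (b in seq_along(batch)) {
    e <- batch[[b]]
    r0 <- offsets[b]
    l <- lens[b]
    pos[r0 + seq_len(l)] <- seq_len(l) - 1L
    if (cl > 0L) {
      v <- pmin(as.integer(e$cond), COUNT_CLIP)
      val_rows <- c(val_rows, r0 + seq_len(cl))
      val_ids <- c(val_ids, v + 1L)
      chan_rows <- c(chan_rows, r0 + seq_len(cl))
      chan_ids <- c(chan_ids, seq_len(cl))
      seg[r0 + seq_len(cl)] <- 1L
    }
    smi_rows <- r0 + cl + seq_along(e$ids)
    tok_rows <- c(tok_rows, smi_rows)
    tok_ids <- c(tok_ids, e$ids)
    seg[smi_rows] <- 2L
  }
  x[tok_rows, ] <- params$tok_emb[tok_ids, , drop = FALSE]
  if (length(val_rows)) {
    x[val_rows, ] <- params$val_emb[val_ids, , drop = FALSE] +
      params$chan_emb[chan_ids, , drop = FALSE]
  }
  x <- x + params$seg_emb[seg, , drop = FALSE]
  list(x = x, pos = pos, lens = lens, offsets = offsets, seg = seg,
       tok_rows = tok_rows, tok_ids = tok_ids,
       val_rows = val_rows, val_ids = val_ids, chan_ids = chan_ids)
}

# Full transformer stack over concatenated rows; returns final hidden
# states and (optionally) caches for the backward pass.
stack_fwd <- function(params, config, emb, keep_cache = FALSE,
                      drop_masks = NULL) {
  d <- config$embed_dim
  h <- config$n_heads
  dh <- d %/% h
  scale <- 1 / sqrt(dh)
  tabs <- rope_tables(emb$pos, dh, config$rope_theta)
  x <- emb$x
  caches <- if (keep_cache) vector("list", config$n_layers)
  nseq <- length(emb$lens)
  for (l in seq_len(config$n_layers)) {
    ln1 <- ln_fwd(x, params[[paste0("ln1_g", l)]],
                  params[[paste0("ln1_b", l)]])
    qkv <- ln1$y %*% params[[paste0("w_qkv", l)]]
    qkv <- qkv + rep(params[[paste0("b_qkv", l)]], each = nrow(qkv))
    att_out <- matrix(0, nrow(x), d)
    att_cache <- if (keep_cache) vector("list", nseq * h)
    q_rot_all <- matrix(0, nrow(x), d)
    k_rot_all <- matrix(0, nrow(x), d)
    for (hd in seq_len(h)) {
      cq <- (hd - 1L) * dh + seq_len(dh)
      q_rot_all[, cq] <- rope_rows(qkv[, cq, drop = FALSE], tabs)
      k_rot_all[, cq] <- rope_rows(qkv[, d + cq, drop = FALSE], tabs)
    }
    for (b in seq_len(nseq)) {
      rows <- emb$offsets[b] + seq_len(emb$lens[b])
      for (hd in seq_len(h)) {
        cq <- (hd - 1L) * dh + seq_len(dh)
        qm <- q_rot_all[rows, cq, drop = FALSE]
        km <- k_rot_all[rows, cq, drop = FALSE]
        vm <- qkv[rows, 2L * d + cq, drop = FALSE]
        s <- (qm %*% t(km)) * scale
        s[causal_mask_idx(nrow(s))] <- -Inf
        a <- exp(s - rowmax_masked(s))
        a <- a / rowSums(a)
        att_out[rows, cq] <- a %*% vm
        if (keep_cache) att_cache[[(b - 1L) * h + hd]] <- a
      }
    }
    proj <- att_out %*% params[[paste0("w_o", l)]]
    proj <- proj + rep(params[[paste0("b_o", l)]], each = nrow(proj))
    dm_a <- if (is.null(drop_masks)) NULL else drop_masks[[l]]$att
    if (!is.null(dm_a)) proj <- proj * dm_a
    x1 <- x + proj
    ln2 <- ln_fwd(x1, params[[paste0("ln2_g", l)]],
                  params[[paste0("ln2_b", l)]])
    f1 <- ln2$y %*% params[[paste0("w_f1", l)]]
    f1 <- f1 + rep(params[[paste0("b_f1", l)]], each = nrow(f1))
    f1_pn <- stats::pnorm(f1)
    f1_act <- f1 * f1_pn
    f2 <- f1_act %*% params[[paste0("w_f2", l)]]
    f2 <- f2 + rep(params[[paste0("b_f2", l)]], each = nrow(f2))
    dm_f <- if (is.null(drop_masks)) NULL else drop_masks[[l]]$ff
    if (!is.null(dm_f)) f2 <- f2 * dm_f
    x_new <- x1 + f2
    if (keep_cache) {
      caches[[l]] <- list(ln1 = ln1, qkv = qkv, q_rot = q_rot_all,
                          k_rot = k_rot_all, att_out = att_out,
                          att = att_cache, x_in = x, x1 = x1, ln2 = ln2,
                          f1 = f1, f1_pn = f1_pn, f1_act = f1_act)
    }
    x <- x_new
  }
  lnf <- ln_fwd(x, params$lnf_g, params$lnf_b)
  list(h = lnf$y, lnf = lnf, x_last = x, caches = caches, tabs = tabs)
}

softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# Loss + gradients for one batch (training core).
loss_and_grads <- function(params, config, batch, drop_masks = NULL) {
  cl <- condition_length(config)
  emb <- embed_batch(params, config, batch)
  fw <- stack_fwd(params, config, emb, keep_cache = TRUE,
                  drop_masks = drop_masks)
  # prediction rows: positions C+1 .. C+len(ids) of each sequence
  pred_rows <- integer(0)
  targets <- integer(0)
  for (b in seq_along(batch)) {
    e <- batch[[b]]
    r0 <- emb$offsets[b]
    pred_rows <- c(pred_rows, r0 + cl + seq_along(e$ids))
    targets <- c(targets, e$targets)
  }
  hsel <- fw$h[pred_rows, , drop = FALSE]
  z <- hsel %*% params$w_out
  z <- z + rep(params$b_out, each = nrow(z))
  p <- softmax_rows(z)
  m <- nrow(z)
  loss <- -mean(log(pmax(p[cbind(seq_len(m), targets)], 1e-12)))
  dz <- p
  dz[cbind(seq_len(m), targets)] <- dz[cbind(seq_len(m), targets)] - 1
  dz <- dz / m
  g <- lapply(params, function(x) if (is.matrix(x)) {
    matrix(0, nrow(x), ncol(x))
  } else numeric(length(x)))
  g$w_out <- t(hsel) %*% dz
  g$b_out <- colSums(dz)
  dh_sel <- dz %*% t(params$w_out)
  dh_full <- matrix(0, nrow(fw$h), config$embed_dim)
  dh_full[pred_rows, ] <- dh_sel
  lb <- ln_bwd(dh_full, fw$lnf, params$lnf_g)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  dx <- lb$dx
  d <- config$embed_dim
  h <- config$n_heads
  dh_ <- d %/% h
  scale <- 1 / sqrt(dh_)
  nseq <- length(emb$lens)
  for (l in rev(seq_len(config$n_layers))) {
    ca <- fw$caches[[l]]
    dm_f <- if (is.null(drop_masks)) NULL else drop_masks[[l]]$ff
    df2 <- if (is.null(dm_f)) dx else dx * dm_f
    dgelu_in <- (df2 %*% t(params[[paste0("w_f2", l)]])) *
      (ca$f1_pn + ca$f1 * stats::dnorm(ca$f1))
    g[[paste0("w_f2", l)]] <- t(ca$f1_act) %*% df2
    g[[paste0("b_f2", l)]] <- colSums(df2)
    g[[paste0("w_f1", l)]] <- t(ca$ln2$y) %*% dgelu_in
    g[[paste0("b_f1", l)]] <- colSums(dgelu_in)
    dln2y <- dgelu_in %*% t(params[[paste0("w_f1", l)]])
    lb2 <- ln_bwd(dln2y, ca$ln2, params[[paste0("ln2_g", l)]])
    g[[paste0("ln2_g", l)]] <- lb2$dg
    g[[paste0("ln2_b", l)]] <- lb2$db
    dx1 <- dx + lb2$dx
    dm_a <- if (is.null(drop_masks)) NULL else drop_masks[[l]]$att
    dproj <- if (is.null(dm_a)) dx1 else dx1 * dm_a
    g[[paste0("w_o", l)]] <- t(ca$att_out) %*% dproj
    g[[paste0("b_o", l)]] <- colSums(dproj)
    datt <- dproj %*% t(params[[paste0("w_o", l)]])
    dqkv <- matrix(0, nrow(dx), 3L * d)
    for (b in seq_len(nseq)) {
      rows <- emb$offsets[b] + seq_len(emb$lens[b])
      for (hd in seq_len(h)) {
        cq <- (hd - 1L) * dh_ + seq_len(dh_)
        a <- ca$att[[(b - 1L) * h + hd]]
        vm <- ca$qkv[rows, 2L * d + cq, drop = FALSE]
        dout <- datt[rows, cq, drop = FALSE]
        da <- dout %*% t(vm)
        dqkv[rows, 2L * d + cq] <- t(a) %*% dout
        ds <- a * (da - rowSums(da * a))
        qm <- ca$q_rot[rows, cq, drop = FALSE]
        km <- ca$k_rot[rows, cq, drop = FALSE]
        dq_rot <- (ds %*% km) * scale
        dk_rot <- (t(ds) %*% qm) * scale
        tabs_b <- list(co = fw$tabs$co[rows, , drop = FALSE],
                       si = fw$tabs$si[rows, , drop = FALSE])
        dqkv[rows, cq] <- rope_rows_bwd(dq_rot, tabs_b)
        dqkv[rows, d + cq] <- rope_rows_bwd(dk_rot, tabs_b)
      }
    }
    g[[paste0("w_qkv", l)]] <- t(ca$ln1$y) %*% dqkv
    g[[paste0("b_qkv", l)]] <- colSums(dqkv)
    dln1y <- dqkv %*% t(params[[paste0("w_qkv", l)]])
    lb1 <- ln_bwd(dln1y, ca$ln1, params[[paste0("ln1_g", l)]])
    g[[paste0("ln1_g", l)]] <- lb1$dg
    g[[paste0("ln1_b", l)]] <- lb1$db
    dx <- dx1 + lb1$dx
  }
  # embedding gradients
  seg_acc <- rowsum(dx, emb$seg)
  g$seg_emb[as.integer(rownames(seg_acc)), ] <- seg_acc
  tok_acc <- rowsum(dx[emb$tok_rows, , drop = FALSE], emb$tok_ids)
  g$tok_emb[as.integer(rownames(tok_acc)), ] <- tok_acc
  if (length(emb$val_rows)) {
    val_acc <- rowsum(dx[emb$val_rows, , drop = FALSE], emb$val_ids)
    g$val_emb[as.integer(rownames(val_acc)), ] <- val_acc
    chan_acc <- rowsum(dx[emb$val_rows, , drop = FALSE], emb$chan_ids)
    g$chan_emb[as.integer(rownames(chan_acc)), ] <- chan_acc
  }
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

prepare_example <- function(smiles, condition, config, vocab) {
  toks <- tokenize_smiles(smiles, vocab)
  ids <- encode_tokens(toks, vocab) # begin + tokens
  pad_id <- unname(vocab$ids[vocab$pad])
  cl <- condition_length(config)
  if (cl > 0L) {
    condition <- as.integer(condition)
    if (length(condition) != cl) {
      stop("condition length ", length(condition),
           " does not match condition_kind ", config$condition_kind)
    }
  } else {
    condition <- integer(0)
  }
  if (cl + length(ids) + 1L > config$max_seq_len) {
    stop("sequence longer than max_seq_len: ", smiles)
  }
  list(cond = condition, ids = ids,
       targets = c(ids[-1L], pad_id))
}

#' Train the conditional SMILES decoder
#'
#' Minimises next-token cross-entropy over SMILES positions (the
#' condition prefix is never a prediction target) with Adam.
#' Deterministic for a fixed `config$seed`, corpus and hyperparameters.
#'
#' @param corpus A data frame with a SMILES column and (unless
#'   `condition_kind = "none"`) a list-column `condition` holding one
#'   numeric/integer condition vector per molecule, e.g. a `phore_fp` or
#'   a count vector.
#' @param config A [decoder_config()].
#' @param smiles_col Column holding SMILES strings.
#' @param epochs,batch_size,lr Training hyperparameters. The defaults
#'   suit small overfitting corpora; all are overridable. `lr` may be a
#'   vector of per-epoch learning rates (recycled to `epochs`), e.g. a
#'   step-decay schedule.
#' @param vocab Vocabulary used for tokenization (pruned by default).
#' @param verbose Print per-epoch loss.
#' @return An object of class `phore_decoder` with elements `params`,
#'   `config`, `vocab_hash`, `loss_trace` (per-epoch mean training
#'   loss) and `n_params`.
#' @export
train_decoder <- function(corpus, config = decoder_config(),
                          smiles_col = smiles, epochs = 60L,
                          batch_size = 16L, lr = 1e-3,
                          vocab = smiles_vocabulary(), verbose = FALSE) {
  corpus <- tibble::as_tibble(corpus)
  smi <- dplyr::pull(corpus, {{ smiles_col }})
  if (!length(smi)) stop("empty corpus")
  cl <- condition_length(config)
  conds <- if (cl > 0L) {
    if (!"condition" %in% names(corpus)) {
      stop("corpus must carry a `condition` list-column for ",
           config$condition_kind)
    }
    corpus$condition
  } else {
    rep(list(integer(0)), length(smi))
  }
  examples <- Map(prepare_example, smi, conds,
                  MoreArgs = list(config = config, vocab = vocab))
  vocab_size <- length(vocab$ids)
  withr::with_seed(config$seed, {
    params <- init_params(config, vocab_size)
    st <- adam_init(params)
    trace <- numeric(epochs)
    lr_ep <- rep_len(lr, epochs)
    n <- length(examples)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        masks <- make_drop_masks(params, config, examples[idx])
        lg <- loss_and_grads(params, config, examples[idx], masks)
        upd <- adam_step(params, lg$grads, st, lr_ep[ep])
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + lg$loss
        nb <- nb + 1L
      }
      trace[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, trace[ep]))
    }
  })
  structure(list(params = params, config = config,
                 vocab_hash = vocab_hash(vocab), loss_trace = trace,
                 n_params = sum(vapply(params, length, integer(1)))),
            class = "phore_decoder")
}

make_drop_masks <- function(params, config, batch) {
  n_rows <- sum(vapply(batch, function(e)
    condition_length(config) + length(e$ids), integer(1)))
  lapply(seq_len(config$n_layers), function(l) {
    if (config$dropout <= 0) return(list(att = NULL, ff = NULL))
    keep <- 1 - config$dropout
    list(att = matrix(stats::rbinom(n_rows * config$embed_dim, 1, keep) /
                        keep, n_rows, config$embed_dim),
         ff = matrix(stats::rbinom(n_rows * config$embed_dim, 1, keep) /
                       keep, n_rows, config$embed_dim))
  })
}

#' @export
print.phore_decoder <- function(x, ...) {
  cat("<phore_decoder> ", x$config$n_layers, " layers, ",
      x$config$n_heads, " heads, d=", x$config$embed_dim,
      ", condition=", x$config$condition_kind, ", ",
      format(x$n_params, big.mark = ","), " parameters\n",
      "final training loss: ",
      round(x$loss_trace[length(x$loss_trace)], 4), "\n", sep = "")
  invisible(x)
}

#' Next-token distributions for a conditioned sequence
#'
#' Runs the decoder over the condition prefix plus token ids and returns
#' the probability distribution over the vocabulary at every position.
#' Causality holds: the row at position p depends only on the condition
#' and tokens at positions <= p.
#'
#' @param model A trained [train_decoder()] object.
#' @param condition Condition vector matching the model's
#'   `condition_kind` (ignored for `"none"`).
#' @param ids Integer input token ids (typically from
#'   [encode_tokens()]).
#' @return A matrix with one row per input position (condition prefix
#'   first, then tokens); each row is a probability vector over the
#'   vocabulary (including pad).
#' @export
decoder_forward <- function(model, condition = NULL, ids) {
  stopifnot(inherits(model, "phore_decoder"))
  config <- model$config
  cl <- condition_length(config)
  cond <- if (cl > 0L) {
    if (is.null(condition)) stop("model expects a condition vector")
    if (length(condition) != cl) {
      stop("condition length must be ", cl)
    }
    as.integer(condition)
  } else integer(0)
  if (cl + length(ids) > config$max_seq_len) {
    stop("sequence longer than max_seq_len")
  }
  batch <- list(list(cond = cond, ids = as.integer(ids),
                     targets = integer(length(ids))))
  emb <- embed_batch(model$params, config, batch)
  fw <- stack_fwd(model$params, config, emb)
  z <- fw$h %*% model$params$w_out
  z <- z + rep(model$params$b_out, each = nrow(z))
  softmax_rows(z)
}

# batched variant used by the sampler: list of (cond, ids) with equal id
# lengths not required; returns list of last-position probability rows.
decoder_next_probs <- function(model, conds, ids_list, temperature = 1) {
  config <- model$config
  cl <- condition_length(config)
  batch <- Map(function(cond, ids) {
    list(cond = if (cl > 0L) as.integer(cond) else integer(0),
         ids = as.integer(ids), targets = integer(length(ids)))
  }, conds, ids_list)
  emb <- embed_batch(model$params, config, batch)
  fw <- stack_fwd(model$params, config, emb)
  last_rows <- emb$offsets[seq_along(batch)] +
    vapply(batch, function(e) cl + length(e$ids), integer(1))
  z <- fw$h[last_rows, , drop = FALSE] %*% model$params$w_out
  z <- z + rep(model$params$b_out, each = nrow(z))
  softmax_rows(z / temperature)
}

#' Serialize / restore a trained decoder
#'
#' `save_decoder()` writes parameters plus configuration;
#' `load_decoder()` restores them and refuses to load against a
#' vocabulary whose content hash differs from the one the model was
#' trained with.
#'
#' @param model A `phore_decoder`.
#' @param path File path.
#' @inheritParams train_decoder
#' @return `load_decoder()` returns the restored `phore_decoder`.
#' @export
save_decoder <- function(model, path) {
  stopifnot(inherits(model, "phore_decoder"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path, vocab = smiles_vocabulary()) {
  obj <- readRDS(path)
  if (!isTRUE(all.equal(obj$vocab_hash, vocab_hash(vocab)))) {
    stop("vocabulary hash mismatch: checkpoint was trained with a ",
         "different vocabulary")
  }
  structure(obj, class = "phore_decoder")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.phore_decoder <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @exportS3Method generics::glance
glance.phore_decoder <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers, n_heads = x$config$n_heads,
    embed_dim = x$config$embed_dim,
    condition_kind = x$config$condition_kind,
    n_params = x$n_params,
    epochs = length(x$loss_trace),
    initial_loss = x$loss_trace[1],
    final_loss = x$loss_trace[length(x$loss_trace)])
}

#' @exportS3Method ggplot2::autoplot
autoplot.phore_decoder <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean training loss",
                  title = "decoder training loss") +
    ggplot2::theme_minimal()
}
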