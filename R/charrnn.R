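# Character-level LSTM language model over SMILES, used to oversample the
# minority class. Stacked LSTM with inter-layer dropout and a softmax
# next-token head, trained by teacher-forced maximum likelihood (next-token
# cross-entropy) with Adam; sampling draws from the temperature-scaled
# softmax from BEGIN until END. Forward/backward-through-time are written on
# base-R matrix operations.

BOS <- "<bos>"; EOS <- "<eos>"; PAD <- "<pad>"

#' Build a SMILES token vocabulary
#'
#' Tokens are single characters except the two-character element symbols
#' `Cl` and `Br`, which are atomic tokens; BEGIN/END/PAD specials are
#' appended after the sorted corpus tokens. Tokenization is lossless:
#' `detokenize(tokenize(s)) == s` for every corpus string.
#'
#' @param corpus non-empty character vector of SMILES.
#' @return list of class `token_vocabulary` with `tokens` and the special
#'   indices `bos`, `eos`, `pad`.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) > 0)
  toks <- sort(unique(unlist(lapply(corpus, smiles_tokens))))
  tokens <- c(toks, BOS, EOS, PAD)
  structure(list(tokens = tokens,
                 bos = length(toks) + 1L, eos = length(toks) + 2L,
                 pad = length(toks) + 3L),
            class = "token_vocabulary")
}

#' Tokenize / detokenize SMILES under a vocabulary
#'
#' @param vocab a `token_vocabulary`.
#' @param s a single SMILES string.
#' @return `tokenize()`: integer index vector (error on out-of-vocabulary
#'   units); `detokenize()`: the string.
#' @export
tokenize <- function(vocab, s) {
  idx <- match(smiles_tokens(s), vocab$tokens)
  if (anyNA(idx)) stop("string contains tokens outside the vocabulary: ", s)
  idx
}

#' @rdname tokenize
#' @param idx integer token indices.
#' @export
detokenize <- function(vocab, idx) {
  paste(vocab$tokens[idx], collapse = "")
}

#' CharRNN configuration
#'
#' Defaults follow the reference generator: three LSTM layers of hidden
#' size 600, dropout 0.2 between intermediate layers, softmax output,
#' batch size 64, Adam at learning rate 0.001, 50 epochs.
#'
#' @param n_layers number of stacked LSTM layers.
#' @param hidden_size LSTM hidden dimension.
#' @param dropout_rate dropout between intermediate layers (training only).
#' @param learning_rate Adam step size.
#' @param batch_size sequences per minibatch.
#' @param epochs training epochs.
#' @param seed RNG seed (initialization, shuffling, dropout, sampling).
#' @param max_sample_length hard cap on sampled sequence length (tokens).
#' @param temperature softmax temperature used when sampling.
#' @export
charrnn_config <- function(n_layers = 3L, hidden_size = 600L,
                           dropout_rate = 0.2, learning_rate = 0.001,
                           batch_size = 64L, epochs = 50L, seed = 1L,
                           max_sample_length = 120L, temperature = 1.0) {
  stopifnot(n_layers >= 1, hidden_size >= 1, dropout_rate >= 0,
            dropout_rate < 1, temperature > 0)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_size = as.integer(hidden_size),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 max_sample_length = as.integer(max_sample_length),
                 temperature = temperature),
            class = "charrnn_config")
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(V, cfg) {
  H <- cfg$hidden_size
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    inp <- if (l == 1L) V else H
    b <- rep(0, 4L * H)
    b[(H + 1L):(2L * H)] <- 1  # forget-gate bias init
    list(Wx = mk(inp, 4L * H), Wh = mk(H, 4L * H), b = b)
  })
  list(layers = layers, Why = mk(H, V), by = rep(0, V))
}

# one LSTM timestep for layer params `p`; x: B x inp, h/c: B x H
lstm_step <- function(p, x, h, c_) {
  H <- ncol(h)
  z <- x %*% p$Wx + h %*% p$Wh
  z <- sweep(z, 2L, p$b, "+")
  i <- sigm(z[, 1:H, drop = FALSE])
  f <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f * c_ + i * g
  tc <- tanh(c_new)
  list(i = i, f = f, g = g, o = o, c = c_new, tc = tc, h = o * tc)
}

# forward + loss + gradients for one padded batch.
# seqs: list of integer token vectors (without BOS/EOS).
charrnn_batch_grad <- function(params, seqs, vocab, cfg, train = TRUE) {
  V <- length(vocab$tokens); H <- cfg$hidden_size; L <- cfg$n_layers
  B <- length(seqs)
  lens <- vapply(seqs, length, integer(1)) + 1L  # + EOS target
  Tm <- max(lens)
  # input ids: BOS then tokens (padded); target ids: tokens then EOS
  inp <- matrix(vocab$pad, B, Tm); tgt <- matrix(vocab$pad, B, Tm)
  for (b in seq_len(B)) {
    s <- seqs[[b]]
    inp[b, 1:lens[b]] <- c(vocab$bos, s)
    tgt[b, 1:lens[b]] <- c(s, vocab$eos)
  }
  mask <- tgt != vocab$pad
  n_tok <- sum(mask)

  hs <- cs <- gates <- xs <- dmask <- vector("list", Tm)
  h <- lapply(seq_len(L), function(l) matrix(0, B, H))
  c_ <- lapply(seq_len(L), function(l) matrix(0, B, H))
  loss <- 0
  dWhy <- params$Why * 0; dby <- params$by * 0
  dlogits_store <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    x <- matrix(0, B, V); x[cbind(seq_len(B), inp[, t])] <- 1
    xs_t <- vector("list", L); g_t <- vector("list", L); dm_t <- vector("list", L)
    for (l in seq_len(L)) {
      xs_t[[l]] <- x
      st <- lstm_step(params$layers[[l]], x, h[[l]], c_[[l]])
      g_t[[l]] <- st
      h[[l]] <- st$h; c_[[l]] <- st$c
      x <- st$h
      if (l < L && train && cfg$dropout_rate > 0) {
        m <- matrix(stats::runif(B * H) >= cfg$dropout_rate, B, H)
        x <- x * m / (1 - cfg$dropout_rate)
        dm_t[[l]] <- m
      }
    }
    logits <- sweep(x %*% params$Why, 2L, params$by, "+")
    logits <- logits - apply(logits, 1, max)
    ex <- exp(logits); p <- ex / rowSums(ex)
    rowsel <- cbind(seq_len(B), tgt[, t])
    lt <- -log(pmax(p[rowsel], 1e-12)) * mask[, t]
    loss <- loss + sum(lt)
    dlog <- p
    dlog[rowsel] <- dlog[rowsel] - 1
    dlog <- dlog * mask[, t] / n_tok
    dWhy <- dWhy + crossprod(x, dlog)
    dby <- dby + colSums(dlog)
    dlogits_store[[t]] <- dlog
    xs[[t]] <- xs_t; gates[[t]] <- g_t; dmask[[t]] <- dm_t
    hs[[t]] <- h; cs[[t]] <- c_
  }
  loss <- loss / n_tok
  if (!train) return(list(loss = loss))

  # backward through time
  gl <- lapply(params$layers, function(p) list(Wx = p$Wx * 0, Wh = p$Wh * 0,
                                               b = p$b * 0))
  dh_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, B, H))
  for (t in rev(seq_len(Tm))) {
    # gradient into the top layer output at time t: softmax head + t+1 carry
    dh <- vector("list", L)
    dh[[L]] <- dlogits_store[[t]] %*% t(params$Why) + dh_next[[L]]
    for (l in rev(seq_len(L))) {
      st <- gates[[t]][[l]]
      dht <- dh[[l]]
      dct <- dc_next[[l]] + dht * st$o * (1 - st$tc^2)
      do_ <- dht * st$tc
      c_prev <- if (t > 1L) cs[[t - 1L]][[l]] else matrix(0, B, H)
      h_prev <- if (t > 1L) hs[[t - 1L]][[l]] else matrix(0, B, H)
      di <- dct * st$g; df <- dct * c_prev; dg <- dct * st$i
      dz <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                  dg * (1 - st$g^2), do_ * st$o * (1 - st$o))
      gl[[l]]$Wx <- gl[[l]]$Wx + crossprod(xs[[t]][[l]], dz)
      gl[[l]]$Wh <- gl[[l]]$Wh + crossprod(h_prev, dz)
      gl[[l]]$b <- gl[[l]]$b + colSums(dz)
      dh_next[[l]] <- dz %*% t(params$layers[[l]]$Wh)
      dc_next[[l]] <- dct * st$f
      if (l > 1L) {
        dx <- dz %*% t(params$layers[[l]]$Wx)
        if (!is.null(dmask[[t]][[l - 1L]])) {
          dx <- dx * dmask[[t]][[l - 1L]] / (1 - cfg$dropout_rate)
        }
        dh[[l - 1L]] <- dx + dh_next[[l - 1L]]
      }
    }
  }
  list(loss = loss, grads = list(layers = gl, Why = dWhy, dby = dby))
}

#' Train the SMILES generator
#'
#' @param corpus character vector of (canonical) SMILES; the vocabulary is
#'   built from it unless supplied.
#' @param cfg a [charrnn_config()].
#' @param vocab optional pre-built `token_vocabulary`.
#' @return a `generator_model`: vocabulary, config, trained parameters and
#'   per-epoch training loss in `$history`.
#' @export
train_generator <- function(corpus, cfg = charrnn_config(), vocab = NULL) {
  if (!length(corpus)) stop("empty training corpus")
  if (is.null(vocab)) vocab <- build_vocabulary(corpus)
  seqs <- lapply(corpus, function(s) tokenize(vocab, s))
  V <- length(vocab$tokens)
  with_seed(cfg$seed, {
    params <- lstm_init(V, cfg)
    # flat Adam state over all parameter matrices
    flat_names <- c(unlist(lapply(seq_len(cfg$n_layers), function(l)
      paste0("l", l, c("Wx", "Wh", "b")))), "Why", "by")
    getp <- function(nm) {
      if (nm == "Why") return(params$Why)
      if (nm == "by") return(params$by)
      l <- as.integer(substr(nm, 2, 2))
      params$layers[[l]][[substr(nm, 3, nchar(nm))]]
    }
    setp <- function(nm, val) {
      if (nm == "Why") params$Why <<- val
      else if (nm == "by") params$by <<- val
      else {
        l <- as.integer(substr(nm, 2, 2))
        params$layers[[l]][[substr(nm, 3, nchar(nm))]] <<- val
      }
    }
    mstate <- lapply(flat_names, function(nm) {
      p <- getp(nm); list(m = p * 0, v = p * 0)
    })
    names(mstate) <- flat_names
    t_step <- 0L
    history <- numeric(0)
    n <- length(seqs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0; ep_n <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        res <- charrnn_batch_grad(params, seqs[idx], vocab, cfg)
        ep_loss <- ep_loss + res$loss * length(idx); ep_n <- ep_n + length(idx)
        t_step <- t_step + 1L
        gr <- res$grads
        for (nm in flat_names) {
          g <- if (nm == "Why") gr$Why else if (nm == "by") gr$dby else {
            l <- as.integer(substr(nm, 2, 2))
            gr$layers[[l]][[substr(nm, 3, nchar(nm))]]
          }
          st <- mstate[[nm]]
          st$m <- 0.9 * st$m + 0.1 * g
          st$v <- 0.999 * st$v + 0.001 * g^2
          mhat <- st$m / (1 - 0.9^t_step)
          vhat <- st$v / (1 - 0.999^t_step)
          setp(nm, getp(nm) - cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8))
          mstate[[nm]] <- st
        }
      }
      history <- c(history, ep_loss / ep_n)
    }
    structure(list(vocabulary = vocab, config = cfg, params = params,
                   history = history),
              class = "generator_model")
  })
}

#' Next-token probability distribution
#'
#' One forward step of the generator; exposed mainly for inspection and
#' testing (distributions sum to 1).
#'
#' @param model a `generator_model`.
#' @param prefix_idx integer token indices consumed so far (excluding BOS).
#' @param temperature softmax temperature.
#' @return named numeric probability vector over the vocabulary.
#' @export
next_token_distribution <- function(model, prefix_idx = integer(0),
                                    temperature = 1.0) {
  vocab <- model$vocabulary; cfg <- model$config
  V <- length(vocab$tokens); H <- cfg$hidden_size; L <- cfg$n_layers
  h <- lapply(seq_len(L), function(l) matrix(0, 1, H))
  c_ <- lapply(seq_len(L), function(l) matrix(0, 1, H))
  seq_in <- c(vocab$bos, prefix_idx)
  for (tok in seq_in) {
    x <- matrix(0, 1, V); x[1, tok] <- 1
    for (l in seq_len(L)) {
      st <- lstm_step(model$params$layers[[l]], x, h[[l]], c_[[l]])
      h[[l]] <- st$h; c_[[l]] <- st$c; x <- st$h
    }
  }
  logits <- as.numeric(x %*% model$params$Why + model$params$by)
  logits[c(vocab$bos, vocab$pad)] <- -Inf  # never emit specials except EOS
  z <- logits / temperature
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  names(p) <- vocab$tokens
  p
}

#' Sample SMILES strings from the generator
#'
#' Each sequence starts at BEGIN and draws from the temperature-scaled
#' softmax until END or `max_sample_length`; BEGIN and PAD are masked out
#' of the sampling distribution. Returned strings are raw (validity not
#' guaranteed). The whole batch is rolled out simultaneously under the seed.
#'
#' @param model a `generator_model`.
#' @param n number of sequences to draw.
#' @param seed RNG seed for the sampling stream.
#' @param temperature overrides the config temperature when given.
#' @param greedy take the argmax at each step instead of sampling.
#' @return character vector of length `n`.
#' @export
sample_smiles <- function(model, n, seed = model$config$seed,
                          temperature = model$config$temperature,
                          greedy = FALSE) {
  if (n == 0) return(character(0))
  vocab <- model$vocabulary; cfg <- model$config
  V <- length(vocab$tokens); H <- cfg$hidden_size; L <- cfg$n_layers
  with_seed(seed, {
    h <- lapply(seq_len(L), function(l) matrix(0, n, H))
    c_ <- lapply(seq_len(L), function(l) matrix(0, n, H))
    cur <- rep(vocab$bos, n)
    alive <- rep(TRUE, n)
    out <- vector("list", n)
    for (step in seq_len(cfg$max_sample_length)) {
      x <- matrix(0, n, V); x[cbind(seq_len(n), cur)] <- 1
      for (l in seq_len(L)) {
        st <- lstm_step(model$params$layers[[l]], x, h[[l]], c_[[l]])
        h[[l]] <- st$h; c_[[l]] <- st$c; x <- st$h
      }
      logits <- sweep(x %*% model$params$Why, 2L, model$params$by, "+")
      logits[, c(vocab$bos, vocab$pad)] <- -Inf
      z <- logits / temperature
      z <- z - apply(z, 1, max)
      p <- exp(z); p <- p / rowSums(p)
      nxt <- if (greedy) max.col(p, ties.method = "first") else {
        vapply(seq_len(n), function(b) {
          sample.int(V, 1L, prob = p[b, ])
        }, integer(1))
      }
      for (b in which(alive)) {
        if (nxt[b] == vocab$eos) alive[b] <- FALSE
        else out[[b]] <- c(out[[b]], nxt[b])
      }
      cur <- nxt
      if (!any(alive)) break
    }
    vapply(out, function(ix) if (is.null(ix)) "" else detokenize(vocab, ix),
           character(1))
  })
}

#' Filter raw generated SMILES into usable minority-class additions
#'
#' Pipeline: standardize (parse failures discarded), drop strings whose
#' canonical SMILES is shorter (in characters) than the shortest training
#' compound, deduplicate canonical SMILES, and drop anything already present
#' in the training corpus or, when supplied, in the opposing class.
#'
#' @param raw character vector of raw generated SMILES.
#' @param training_corpus character vector of (canonical) training SMILES.
#' @param exclude additional canonical SMILES to exclude (e.g. actives).
#' @return data.frame of standardized survivors (`compound_id`,
#'   `canonical_smiles`, `source = "generated"`), with attribute `log`
#'   giving the count removed at each stage.
#' @export
filter_generated <- function(raw, training_corpus, exclude = character(0)) {
  stopifnot(length(training_corpus) > 0)
  std <- standardize_smiles(raw, source = "generated")
  valid <- std[std$ok, , drop = FALSE]
  min_len <- min(nchar(training_corpus))
  long_enough <- valid[nchar(valid$canonical_smiles) >= min_len, , drop = FALSE]
  uniq <- long_enough[!duplicated(long_enough$canonical_smiles), , drop = FALSE]
  keep <- uniq[!(uniq$canonical_smiles %in% c(training_corpus, exclude)), ,
               drop = FALSE]
  res <- data.frame(compound_id = sprintf("gen%d", seq_len(nrow(keep))),
                    canonical_smiles = keep$canonical_smiles,
                    source = rep("generated", nrow(keep)),
                    stringsAsFactors = FALSE)
  attr(res, "log") <- list(n_raw = length(raw), n_valid = nrow(valid),
                           n_long_enough = nrow(long_enough),
                           n_unique = nrow(uniq), n_novel = nrow(keep))
  res
}

#' Generation-quality metrics (MOSES-style)
#'
#' Validity (valid/requested), uniqueness (unique canonical/valid), novelty
#' (fraction of unique not in the training corpus), internal diversity
#' (1 - mean pairwise Tanimoto among the unique generated set) and SNN to
#' train (mean over generated of the maximum Tanimoto to the training set).
#'
#' @param raw character vector of raw generated SMILES (as sampled).
#' @param training_corpus canonical SMILES of the generator's training set.
#' @param config fingerprint configuration for the similarity terms.
#' @return list of class `generation_report`.
#' @export
generation_metrics <- function(raw, training_corpus, config = fp_config()) {
  n_req <- length(raw)
  if (!n_req) {
    warning("no generated molecules; all ratios reported as 0")
    return(structure(list(n_requested = 0L, n_valid = 0L, validity = 0,
                          uniqueness = 0, novelty = 0, internal_diversity = 0,
                          snn_to_train = 0), class = "generation_report"))
  }
  std <- standardize_smiles(raw, source = "generated")
  valid <- std$canonical_smiles[std$ok]
  uniq <- unique(valid)
  validity <- length(valid) / n_req
  uniqueness <- if (length(valid)) length(uniq) / length(valid) else 0
  novelty <- if (length(uniq)) mean(!(uniq %in% training_corpus)) else 0
  internal_diversity <- 0; snn <- 0
  if (length(uniq) >= 2L) {
    fps <- morgan_fingerprints(uniq, config)
    sim <- tanimoto_matrix(fps$bits, fps$bits)
    internal_diversity <- 1 - mean(sim[upper.tri(sim)])
  }
  if (length(uniq) >= 1L && length(training_corpus)) {
    fps <- morgan_fingerprints(uniq, config)
    ref <- morgan_fingerprints(unique(training_corpus), config)
    snn <- mean(apply(tanimoto_matrix(fps$bits, ref$bits), 1, max))
  }
  structure(list(n_requested = n_req, n_valid = length(valid),
                 validity = validity, uniqueness = uniqueness,
                 novelty = novelty, internal_diversity = internal_diversity,
                 snn_to_train = snn),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf(paste0("generation_report: %d/%d valid (%.1f%%), uniqueness ",
                     "%.2f, novelty %.2f,\n  internal diversity %.2f, ",
                     "SNN-to-train %.2f\n"),
              x$n_valid, x$n_requested, 100 * x$validity, x$uniqueness,
              x$novelty, x$internal_diversity, x$snn_to_train))
  invisible(x)
}
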