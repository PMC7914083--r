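# Multi-round cross-modal attention memory encoder and its two decoders.
# A query vector u is refined over r rounds, each round attending first over
# a category fact memory (dot-product scores) and then over a visual fact
# memory (one-layer tanh scorer), adding the softmax-weighted memory readout
# back into u; a final tanh layer produces the encoding e_c. Decoding is
# either generative (an LSTM emitting a category-token distribution per step)
# or discriminative (candidate token sequences encoded by a shared LSTM and
# scored against e_c by dot product).

#' Standard LSTM cell parameters
#'
#' Input, forget and output gates with a tanh candidate; weights drawn
#' uniformly from \code{[-0.1, 0.1]} under \code{seed}.
#'
#' @param input_dim Input vector dimension.
#' @param hidden_dim Hidden state dimension.
#' @param seed Integer seed.
#' @return List with \code{W} (4h x input), \code{U} (4h x h), \code{b} (4h).
#' @export
lstm_params <- function(input_dim, hidden_dim, seed = 1L) {
  with_seed(seed, {
    list(W = matrix(stats::runif(4 * hidden_dim * input_dim, -0.1, 0.1),
                    4 * hidden_dim, input_dim),
         U = matrix(stats::runif(4 * hidden_dim * hidden_dim, -0.1, 0.1),
                    4 * hidden_dim, hidden_dim),
         b = stats::runif(4 * hidden_dim, -0.1, 0.1),
         hidden_dim = hidden_dim, input_dim = input_dim)
  })
}

#' One LSTM step
#'
#' @param params \code{\link{lstm_params}} object.
#' @param x Input vector.
#' @param h,c Previous hidden and cell state (default zero).
#' @return List with new \code{h} and \code{c}.
#' @export
lstm_cell <- function(params, x, h = NULL, c = NULL) {
  hd <- params$hidden_dim
  if (is.null(h)) h <- numeric(hd)
  if (is.null(c)) c <- numeric(hd)
  z <- as.vector(params$W %*% x + params$U %*% h) + params$b
  i <- stats::plogis(z[seq_len(hd)])
  f <- stats::plogis(z[hd + seq_len(hd)])
  g <- tanh(z[2 * hd + seq_len(hd)])
  o <- stats::plogis(z[3 * hd + seq_len(hd)])
  cn <- f * c + i * g
  list(h = o * tanh(cn), c = cn)
}

#' Memory banks for the attention encoder
#'
#' @param category_memory Matrix (c x d): one learned fact row per class.
#' @param visual_memory Matrix (R x d): one fact row per image region
#'   (R = 196 at the 14x14 conv-map scale; the actual map size at desk scale).
#' @return Object of class \code{memory_banks}.
#' @export
memory_banks <- function(category_memory, visual_memory) {
  category_memory <- as.matrix(category_memory)
  visual_memory <- as.matrix(visual_memory)
  if (nrow(category_memory) < 1L || nrow(visual_memory) < 1L) {
    stopf("memory banks need at least one row each")
  }
  if (ncol(category_memory) != ncol(visual_memory)) {
    stopf("both memories must share the embedding dimension d")
  }
  if (!all(is.finite(category_memory)) || !all(is.finite(visual_memory))) {
    stopf("memory rows must be finite")
  }
  structure(list(category_memory = category_memory,
                 visual_memory = visual_memory),
            class = "memory_banks")
}

#' Attention encoder/decoder parameters
#'
#' All weights drawn uniformly from \code{[-0.1, 0.1]} under \code{seed}:
#' the visual scorer (\code{W_fh}, \code{W_u}, \code{b_h}, \code{w_p},
#' \code{b_p}), the output layer (\code{W_e}, \code{b_e}), the shared input
#' encoder \code{lstm_f}, the generative decoder \code{lstm_g} with its
#' vocabulary projection (\code{W_g}, \code{b_g}) and token embedding table
#' \code{token_embed}, and the shared candidate encoder \code{lstm_d}.
#'
#' @param d Embedding dimension of queries and memory rows.
#' @param k Hidden size of the visual attention scorer.
#' @param vocab_size Number of category tokens.
#' @param seed Integer seed.
#' @return Object of class \code{attention_params}.
#' @export
attention_params <- function(d, k, vocab_size = 2L, seed = 1L) {
  assert_scalar_count(d, "d"); assert_scalar_count(k, "k")
  assert_scalar_count(vocab_size, "vocab_size")
  with_seed(seed, {
    u <- function(n) stats::runif(n, -0.1, 0.1)
    structure(list(
      d = d, k = k, vocab_size = vocab_size,
      W_fh = matrix(u(k * d), k, d),
      W_u  = matrix(u(k * d), k, d),
      b_h  = u(k),
      w_p  = u(k),                      # k-vector: one scalar score per region
      b_p  = u(1),
      W_e  = matrix(u(d * d), d, d),
      b_e  = u(d),
      lstm_f = lstm_params(d, d, seed = sample.int(1e6, 1)),
      lstm_g = lstm_params(d, d, seed = sample.int(1e6, 1)),
      lstm_d = lstm_params(d, d, seed = sample.int(1e6, 1)),
      W_g  = matrix(u(vocab_size * d), vocab_size, d),
      b_g  = u(vocab_size),
      token_embed = matrix(u(vocab_size * d), vocab_size, d)
    ), class = "attention_params")
  })
}

#' Encode an input sequence to a query vector
#'
#' Runs the shared recurrent encoder over the sequence from the zero state
#' and returns the final hidden state (the query the attention rounds refine).
#'
#' @param sequence Matrix with one d-vector per row, or a list of d-vectors.
#' @param params An \code{\link{attention_params}} object.
#' @return Numeric d-vector.
#' @export
encode_input <- function(sequence, params) {
  if (is.list(sequence)) sequence <- do.call(rbind, sequence)
  sequence <- as.matrix(sequence)
  if (nrow(sequence) == 0L) stopf("`sequence` must be nonempty")
  h <- NULL; c <- NULL
  for (t in seq_len(nrow(sequence))) {
    st <- lstm_cell(params$lstm_f, sequence[t, ], h, c)
    h <- st$h; c <- st$c
  }
  h
}

#' One category-memory attention round
#'
#' Scores every category fact by its dot product with the query, softmaxes
#' the scores, and adds the weighted fact readout back into the query.
#'
#' @param u Query d-vector.
#' @param memory A \code{\link{memory_banks}} object.
#' @return List with the updated query \code{u} and the attention
#'   \code{weights} (a probability vector over categories).
#' @export
attend_category <- function(u, memory) {
  stopifnot(inherits(memory, "memory_banks"))
  if (!all(is.finite(u))) stopf("`u` must be finite")
  M <- memory$category_memory
  if (ncol(M) != length(u)) stopf("query/memory dimension mismatch")
  s <- as.vector(M %*% u)
  a <- softmax(s)
  list(u = u + as.vector(crossprod(M, a)), weights = a)
}

#' One visual-memory attention round
#'
#' Each region fact is passed, together with the query, through a one-layer
#' tanh network; a shared projection turns each hidden vector into a scalar
#' region score, softmaxed into region probabilities, and the weighted region
#' readout is added into the query.
#'
#' @param u Query d-vector.
#' @param memory A \code{\link{memory_banks}} object.
#' @param params An \code{\link{attention_params}} object.
#' @return List with the updated query \code{u} and region \code{weights}.
#' @export
attend_visual <- function(u, memory, params) {
  stopifnot(inherits(memory, "memory_banks"), inherits(params, "attention_params"))
  M <- memory$visual_memory
  if (ncol(M) != length(u) || ncol(params$W_fh) != length(u)) {
    stopf("query/memory/params dimension mismatch")
  }
  # h: k x R, column i = tanh(W_fh m_i + W_u u + b_h)
  h <- tanh(params$W_fh %*% t(M) + as.vector(params$W_u %*% u) + params$b_h)
  s <- as.vector(params$w_p %*% h) + params$b_p
  p <- softmax(s)
  list(u = u + as.vector(crossprod(M, p)), weights = p)
}

#' Multi-round cross-modal encoding
#'
#' Starting from the query \code{V_fc}, applies \code{rounds} alternating
#' category/visual attention rounds and finishes with the output layer
#' \code{e_c = tanh(W_e u_r + b_e)}.
#'
#' @param V_fc Initial query d-vector (see \code{\link{encode_input}}).
#' @param memory A \code{\link{memory_banks}} object.
#' @param params An \code{\link{attention_params}} object.
#' @param rounds Number of rounds r (>= 0; 0 skips straight to the output
#'   layer).
#' @return Object of class \code{encoder_state}: the final query \code{u},
#'   \code{round}/\code{rounds_total}, the last category and visual attention
#'   weights, and the encoding \code{encoded}.
#' @export
multi_round_encode <- function(V_fc, memory, params, rounds) {
  if (!is.numeric(rounds) || length(rounds) != 1L || rounds < 0 ||
      rounds != round(rounds)) {
    stopf("`rounds` must be a nonnegative integer")
  }
  u <- V_fc
  aw <- NULL; vw <- NULL
  for (j in seq_len(rounds)) {
    st <- attend_category(u, memory)
    u <- st$u; aw <- st$weights
    st <- attend_visual(u, memory, params)
    u <- st$u; vw <- st$weights
  }
  structure(list(u = u, round = as.integer(rounds),
                 rounds_total = as.integer(rounds),
                 last_category_weights = aw, last_visual_weights = vw,
                 encoded = tanh(as.vector(params$W_e %*% u) + params$b_e)),
            class = "encoder_state")
}

#' Generative decoding of a category-token sequence
#'
#' Seeds the decoder LSTM's hidden state with the encoding, then greedily
#' emits up to \code{max_len} tokens; each step produces a softmax
#' distribution over the category vocabulary and feeds the argmax token's
#' embedding back as the next input. Candidate categories are ranked by their
#' probability in descending order.
#'
#' @param e_c Encoding d-vector.
#' @param params An \code{\link{attention_params}} object.
#' @param max_len Maximum number of emitted tokens (>= 1).
#' @return Object of class \code{decoder_output} with \code{token_probs}
#'   (one probability row per step), \code{tokens} (greedy argmax ids), and
#'   \code{ranking} of the vocabulary by first-step probability.
#' @export
generative_decode <- function(e_c, params, max_len = 1L) {
  stopifnot(inherits(params, "attention_params"))
  assert_scalar_count(max_len, "max_len")
  h <- e_c; c <- numeric(length(e_c))
  x <- numeric(length(e_c))             # start-of-sequence: zero embedding
  probs <- matrix(0, max_len, params$vocab_size)
  tokens <- integer(max_len)
  for (i in seq_len(max_len)) {
    st <- lstm_cell(params$lstm_g, x, h, c)
    h <- st$h; c <- st$c
    p <- softmax(as.vector(params$W_g %*% h) + params$b_g)
    probs[i, ] <- p
    tokens[i] <- which.max(p)
    x <- params$token_embed[tokens[i], ]
  }
  structure(list(token_probs = probs, tokens = tokens,
                 ranking = order(probs[1, ], decreasing = TRUE)),
            class = "decoder_output")
}

#' Discriminative decoding over candidate categories
#'
#' Encodes every candidate token sequence with the shared candidate encoder,
#' scores each against the encoding by dot-product similarity, and softmaxes
#' the concatenated scores into a posterior over candidates; candidates sort
#' from large to small posterior.
#'
#' @param e_c Encoding d-vector.
#' @param candidates List of integer token-id sequences (vocabulary indices).
#' @param params An \code{\link{attention_params}} object.
#' @return Object of class \code{decoder_output} with
#'   \code{candidate_scores}, \code{posterior}, and \code{ranking}.
#' @export
discriminative_decode <- function(e_c, candidates, params) {
  stopifnot(inherits(params, "attention_params"))
  if (!is.list(candidates) || length(candidates) == 0L) {
    stopf("`candidates` must be a nonempty list of token sequences")
  }
  enc <- vapply(candidates, function(tok) {
    tok <- as.integer(tok)
    if (any(tok < 1L | tok > params$vocab_size)) stopf("token id out of vocabulary")
    h <- NULL; c <- NULL
    for (t in tok) {
      st <- lstm_cell(params$lstm_d, params$token_embed[t, ], h, c)
      h <- st$h; c <- st$c
    }
    h
  }, numeric(length(e_c)))
  s <- as.vector(e_c %*% enc)
  structure(list(candidate_scores = s, posterior = softmax(s),
                 ranking = order(softmax(s), decreasing = TRUE)),
            class = "decoder_output")
}
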