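# Minimal reverse-mode layer framework backing the fusion model.
#
# A branch is a list of layer specs. Sequence layers (convolutions, pooling,
# dropout, flatten) run per example on an L x C matrix (time/frequency down
# the rows, one column per channel); everything after the flatten runs
# batched on a B x D matrix. Parameters live outside the specs so snapshots
# (early stopping) are plain list copies. Convolution forward/backward are
# compiled (see src/grouped_conv.cpp); the rest is vectorized R.

nn_conv <- function(cin, cout, k, groups = 1L) {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L, k >= 1L)
  list(type = "conv", cin = as.integer(cin), cout = as.integer(cout),
       k = as.integer(k), groups = as.integer(groups),
       pad_left = as.integer((k - 1L) %/% 2L))
}

nn_dense <- function(din, dout) {
  list(type = "dense", din = as.integer(din), dout = as.integer(dout))
}

nn_elu <- function() list(type = "elu")
nn_pool <- function(f) list(type = "pool", f = as.integer(f))
nn_dropout <- function(p) list(type = "dropout", p = p)
nn_flatten <- function() list(type = "flatten")

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_init <- function(layer) {
  switch(layer$type,
    conv = {
      cin_g <- layer$cin %/% layer$groups
      cout_g <- layer$cout %/% layer$groups
      list(W = glorot(c(layer$k, cin_g, layer$cout),
                      layer$k * cin_g, layer$k * cout_g),
           b = numeric(layer$cout))
    },
    dense = list(W = glorot(c(layer$din, layer$dout), layer$din, layer$dout),
                 b = numeric(layer$dout)),
    NULL)
}

layer_forward <- function(layer, params, x, training) {
  switch(layer$type,
    conv = {
      y <- conv1d_fwd(x, params$W, params$b, layer$k, layer$groups,
                      layer$pad_left)
      list(y = y, cache = x)
    },
    dense = {
      y <- x %*% params$W + rep(params$b, each = nrow(x))
      list(y = y, cache = x)
    },
    elu = {
      y <- x
      neg <- which(x < 0)  # which() drops NaN so overflow propagates cleanly
      y[neg] <- exp(x[neg]) - 1
      list(y = y, cache = y)
    },
    pool = {
      f <- layer$f
      L <- nrow(x); C <- ncol(x); Lp <- L %/% f
      xa <- array(x[seq_len(Lp * f), , drop = FALSE], c(f, Lp, C))
      list(y = colMeans(xa), cache = c(L, C))
    },
    dropout = {
      if (!training || layer$p <= 0) {
        list(y = x, cache = NULL)
      } else {
        mask <- (runif(length(x)) >= layer$p) / (1 - layer$p)
        dim(mask) <- dim(x)
        list(y = x * mask, cache = mask)
      }
    },
    flatten = list(y = matrix(as.vector(x), 1L), cache = dim(x))
  )
}

layer_backward <- function(layer, params, cache, dy) {
  switch(layer$type,
    conv = {
      gw <- conv1d_bwd_w(cache, dy, layer$k, layer$groups, layer$pad_left)
      dx <- conv1d_bwd_x(dy, params$W, layer$k, layer$groups,
                         layer$pad_left, layer$cin)
      list(dx = dx, grads = list(W = gw$gw, b = gw$gb))
    },
    dense = {
      list(dx = dy %*% t(params$W),
           grads = list(W = crossprod(cache, dy), b = colSums(dy)))
    },
    elu = {
      d <- dy
      neg <- which(cache < 0)
      d[neg] <- dy[neg] * (cache[neg] + 1)
      list(dx = d, grads = NULL)
    },
    pool = {
      L <- cache[1L]; C <- cache[2L]; f <- layer$f; Lp <- nrow(dy)
      dx <- matrix(0, L, C)
      dx[seq_len(Lp * f), ] <- (dy / f)[rep(seq_len(Lp), each = f), ,
                                        drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = NULL)
      else list(dx = dy * cache, grads = NULL)
    },
    flatten = list(dx = matrix(as.vector(dy), cache[1L], cache[2L]),
                   grads = NULL)
  )
}

# A branch holds the layer specs plus the index of the last per-example
# ("sequence") layer; layers after it operate on the batched B x D matrix.
new_branch <- function(layers, name) {
  n_seq <- 0L
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "flatten") n_seq <- i
  }
  structure(list(layers = layers, n_seq = n_seq, name = name),
            class = "museeg_branch")
}

branch_init <- function(branch) lapply(branch$layers, layer_init)

branch_n_params <- function(params) {
  sum(vapply(params, function(p) {
    if (is.null(p)) 0 else sum(vapply(p, length, numeric(1)))
  }, numeric(1)))
}

# x: for a sequence branch, a list of L x C matrices (one per example);
# for a dense-only branch, a B x D matrix.
branch_forward <- function(branch, params, x, training = FALSE) {
  layers <- branch$layers
  n_seq <- branch$n_seq
  seq_caches <- NULL
  if (n_seq > 0L) {
    B <- length(x)
    seq_caches <- vector("list", B)
    rows <- vector("list", B)
    for (b in seq_len(B)) {
      h <- x[[b]]
      caches <- vector("list", n_seq)
      for (i in seq_len(n_seq)) {
        st <- layer_forward(layers[[i]], params[[i]], h, training)
        h <- st$y
        caches[[i]] <- st$cache
      }
      rows[[b]] <- h
      seq_caches[[b]] <- caches
    }
    X <- do.call(rbind, rows)
  } else {
    X <- x
  }
  head_caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    if (i <= n_seq) next
    st <- layer_forward(layers[[i]], params[[i]], X, training)
    X <- st$y
    head_caches[[i]] <- st$cache
  }
  list(out = X, seq_caches = seq_caches, head_caches = head_caches)
}

branch_backward <- function(branch, params, fw, dout, input_grad = FALSE) {
  layers <- branch$layers
  n_seq <- branch$n_seq
  grads <- vector("list", length(layers))
  dX <- dout
  for (i in rev(seq_along(layers))) {
    if (i <= n_seq) break
    bk <- layer_backward(layers[[i]], params[[i]], fw$head_caches[[i]], dX)
    dX <- bk$dx
    if (!is.null(bk$grads)) grads[[i]] <- bk$grads  # [[<- NULL would drop the slot
  }
  dx_inputs <- NULL
  if (n_seq > 0L) {
    B <- length(fw$seq_caches)
    if (input_grad) dx_inputs <- vector("list", B)
    for (b in seq_len(B)) {
      dh <- dX[b, , drop = FALSE]
      for (i in rev(seq_len(n_seq))) {
        bk <- layer_backward(layers[[i]], params[[i]],
                             fw$seq_caches[[b]][[i]], dh)
        dh <- bk$dx
        if (!is.null(bk$grads)) {
          grads[[i]] <- if (is.null(grads[[i]])) bk$grads else
            Map(`+`, grads[[i]], bk$grads)
        }
      }
      if (input_grad) dx_inputs[[b]] <- dh
    }
  } else if (input_grad) {
    dx_inputs <- dX
  }
  list(grads = grads, dx_inputs = dx_inputs)
}

# ---- Adam optimizer over nested parameter lists -----------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      m <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g * g
      state$m[[i]][[nm]] <- m
      state$v[[i]][[nm]] <- v
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
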