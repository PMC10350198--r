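# Minimal 3D neural-network engine.
#
# There is no deep-learning framework on the R side of this stack, and the
# network itself is the method under study, so the forward and backward
# passes are written here directly. Convolution is expressed as im2col
# gathers followed by matrix multiplication (BLAS does the heavy lifting);
# the gradient with respect to a convolution's input reuses the same gather
# machinery with a flipped, transposed kernel. Activations at convolutional
# stages are stored as (voxels*batch) x channels matrices with rows ordered
# voxel-fastest within subject blocks.

# --- index caches -----------------------------------------------------------

# im2col index table for a 3x3x3 kernel, stride 1, zero padding 1.
# Returns list(idxC: voxels x (27*C) indices into a per-subject padded flat
# volume of length Pp*C; pad_dm; Pp).
conv_index_cache <- function(dm, C) {
  dp <- dm + 2L
  Pp <- prod(dp)
  Vs <- prod(dm)
  ijk <- lin_to_ijk(seq_len(Vs), dm) + 1L   # +1: position inside padded volume
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  idx <- matrix(0L, Vs, 27L)
  for (o in seq_len(27L)) {
    nb <- sweep(ijk, 2, offs[o, ], `+`)
    idx[, o] <- ijk_to_lin(nb, dp)
  }
  idxC <- matrix(0L, Vs, 27L * C)
  for (c in seq_len(C)) idxC[, (c - 1L) * 27L + seq_len(27L)] <- idx + (c - 1L) * Pp
  list(idxC = idxC, pad_dm = dp, Pp = Pp)
}

# interior voxel positions of the unpadded volume inside the padded flat volume
pad_interior_index <- function(dm) {
  dp <- dm + 2L
  ijk <- lin_to_ijk(seq_len(prod(dm)), dm) + 1L
  ijk_to_lin(ijk, dp)
}

# 2x max-pool (ceiling mode) index table: P_out x 8 input linear indices,
# NA where the block sticks out of the volume. An axis of size 1 stays size 1.
pool_index_cache <- function(dm) {
  d2 <- as.integer(ceiling(dm / 2))
  P2 <- prod(d2)
  out_ijk <- lin_to_ijk(seq_len(P2), d2)
  offs <- as.matrix(expand.grid(di = 0:1, dj = 0:1, dk = 0:1))
  idx8 <- matrix(NA_integer_, P2, 8L)
  for (o in seq_len(8L)) {
    nb <- (out_ijk - 1L) * 2L + 1L + matrix(offs[o, ], P2, 3, byrow = TRUE)
    ok <- nb[, 1] <= dm[1] & nb[, 2] <= dm[2] & nb[, 3] <= dm[3]
    idx8[ok, o] <- ijk_to_lin(nb[ok, , drop = FALSE], dm)
  }
  list(idx8 = idx8, dims_out = d2)
}

# gather patches for a batch: P_mat is (Pp*C) x N padded flat activations;
# returns (Vs*N) x (27*C) patch matrix with rows ordered v + (n-1)*Vs
gather_patches <- function(P_mat, idxC, Vs, N) {
  PpC <- nrow(P_mat)
  offs <- (seq_len(N) - 1L) * PpC
  Pvec <- as.vector(P_mat)
  idx_full <- vapply(seq_len(ncol(idxC)),
                     function(j) outer(idxC[, j], offs, `+`),
                     matrix(0, Vs, N))
  matrix(Pvec[idx_full], Vs * N, ncol(idxC))
}

# pad a conv-stage activation matrix A ((Vs*N) x C) into (Pp*C) x N flat form
pad_batch <- function(A, dm, C, N, interior) {
  Vs <- prod(dm)
  Pp <- prod(dm + 2L)
  P_mat <- matrix(0, Pp * C, N)
  rows <- as.vector(outer(interior, (seq_len(C) - 1L) * Pp, `+`))
  for (n in seq_len(N)) {
    a <- A[(n - 1L) * Vs + seq_len(Vs), , drop = FALSE]
    P_mat[rows, n] <- as.vector(a)
  }
  P_mat
}

# flipped/transposed kernel for the input-gradient convolution:
# W is (27*C_in) x C_out; returns (27*C_out) x C_in
flip_kernel <- function(W, C_in, C_out) {
  W2 <- matrix(0, 27L * C_out, C_in)
  for (ci in seq_len(C_in)) for (co in seq_len(C_out)) {
    w <- W[(ci - 1L) * 27L + seq_len(27L), co]
    W2[(co - 1L) * 27L + seq_len(27L), ci] <- rev(w)
  }
  W2
}

# --- layer constructors -----------------------------------------------------

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

layer_conv <- function(dm, C_in, C_out) {
  list(type = "conv", dims = dm, C_in = C_in, C_out = C_out,
       W = he_init(27L * C_in, C_out, 27L * C_in), b = numeric(C_out),
       cache_idx = conv_index_cache(dm, C_in),
       grad_idx = conv_index_cache(dm, C_out),
       interior = pad_interior_index(dm))
}

layer_dense <- function(n_in, n_out) {
  list(type = "dense", W = he_init(n_in, n_out, n_in), b = numeric(n_out))
}

layer_batchnorm <- function(n_feat, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, n_feat), beta = numeric(n_feat),
       rmean = numeric(n_feat), rvar = rep(1, n_feat),
       momentum = momentum, eps = eps)
}

# --- forward / backward -----------------------------------------------------

conv_repr <- function(A, dm, C, N) list(A = A, dims = dm, C = C, N = N)

nn_forward <- function(model, X, train = FALSE) {
  N <- nrow(X)
  repr <- conv_repr(matrix(as.vector(t(X)), ncol = 1L), model$input_shape, 1L, N)
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    L <- model$layers[[li]]
    if (L$type == "conv") {
      Vs <- prod(L$dims)
      P_mat <- pad_batch(repr$A, L$dims, L$C_in, N, L$interior)
      M <- gather_patches(P_mat, L$cache_idx$idxC, Vs, N)
      Y <- M %*% L$W
      Y <- sweep(Y, 2, L$b, `+`)
      caches[[li]] <- list(M = M, in_repr = repr)
      repr <- conv_repr(Y, L$dims, L$C_out, N)
    } else if (L$type == "relu_conv") {
      caches[[li]] <- list(mask = repr$A > 0)
      repr$A <- repr$A * caches[[li]]$mask
    } else if (L$type == "pool") {
      Vs <- prod(L$dims)
      P2 <- prod(L$dims_out)
      best <- matrix(-Inf, P2 * N, repr$C)
      arg <- matrix(0L, P2 * N, repr$C)
      for (p in seq_len(8L)) {
        src <- L$idx8[, p]
        valid <- !is.na(src)
        if (!any(valid)) next
        rows <- as.vector(outer(ifelse(valid, src, 1L), (seq_len(N) - 1L) * Vs, `+`))
        vals <- repr$A[rows, , drop = FALSE]
        vals[rep(!valid, N), ] <- -Inf
        upd <- vals > best
        best[upd] <- vals[upd]
        arg[upd] <- p
      }
      caches[[li]] <- list(arg = arg, dims_in = L$dims, C = repr$C)
      repr <- conv_repr(best, L$dims_out, repr$C, N)
    } else if (L$type == "flatten") {
      Vs <- prod(repr$dims)
      arr <- array(repr$A, c(Vs, N, repr$C))
      Fmat <- matrix(aperm(arr, c(1, 3, 2)), Vs * repr$C, N)
      caches[[li]] <- list(dims = repr$dims, C = repr$C)
      repr <- t(Fmat)
    } else if (L$type == "dense") {
      caches[[li]] <- list(X = repr)
      repr <- sweep(repr %*% L$W, 2, L$b, `+`)
    } else if (L$type == "relu") {
      caches[[li]] <- list(mask = repr > 0)
      repr <- repr * caches[[li]]$mask
    } else if (L$type == "batchnorm") {
      if (train && nrow(repr) > 1) {
        mu <- colMeans(repr)
        va <- colMeans(sweep(repr, 2, mu)^2)
        model$layers[[li]]$rmean <- (1 - L$momentum) * L$rmean + L$momentum * mu
        model$layers[[li]]$rvar <- (1 - L$momentum) * L$rvar + L$momentum * va
      } else {
        mu <- L$rmean; va <- L$rvar
      }
      xc <- sweep(repr, 2, mu)
      istd <- 1 / sqrt(va + L$eps)
      xhat <- sweep(xc, 2, istd, `*`)
      caches[[li]] <- list(xhat = xhat, istd = istd, train = train && nrow(repr) > 1)
      repr <- sweep(sweep(xhat, 2, L$gamma, `*`), 2, L$beta, `+`)
    } else if (L$type == "dropout") {
      if (train && L$rate > 0) {
        mask <- matrix(stats::rbinom(length(repr), 1, 1 - L$rate), nrow(repr)) / (1 - L$rate)
        caches[[li]] <- list(mask = mask)
        repr <- repr * mask
      } else caches[[li]] <- list(mask = NULL)
    } else stop_input("unknown layer type %s", L$type)
    if (identical(li, model$latent_index)) caches$latent <- repr
    if (identical(li, model$last_conv_index))
      caches$last_conv <- if (is.list(repr)) repr$A else repr
  }
  logits <- repr
  pm <- apply(logits, 1, max)
  e <- exp(logits - pm)
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs, caches = caches, N = N, model = model)
}

# Backpropagate d(loss)/d(logits). stop_at: layer index whose OUTPUT gradient
# should be returned (for saliency); need_input_grad returns the gradient at
# the network input as an N x V matrix. Returns list(grads, d_stop, d_input).
nn_backward <- function(fw, dlogits, stop_at = NULL, need_input_grad = FALSE,
                        need_param_grads = TRUE) {
  model <- fw$model
  caches <- fw$caches
  N <- fw$N
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (li in rev(seq_along(model$layers))) {
    if (!is.null(stop_at) && li == stop_at) {
      return(list(grads = grads, d_stop = d, d_input = NULL))
    }
    L <- model$layers[[li]]
    ch <- caches[[li]]
    if (L$type == "dense") {
      if (need_param_grads)
        grads[[li]] <- list(W = crossprod(ch$X, d), b = colSums(d))
      d <- d %*% t(L$W)
    } else if (L$type == "relu") {
      d <- d * ch$mask
    } else if (L$type == "batchnorm") {
      if (need_param_grads)
        grads[[li]] <- list(gamma = colSums(d * ch$xhat), beta = colSums(d))
      if (ch$train) {
        n <- nrow(d)
        dxhat <- sweep(d, 2, L$gamma, `*`)
        d <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(d), byrow = TRUE) -
                     sweep(ch$xhat, 2, colMeans(dxhat * ch$xhat), `*`),
                   2, ch$istd, `*`)
      } else {
        d <- sweep(sweep(d, 2, L$gamma, `*`), 2, ch$istd, `*`)
      }
    } else if (L$type == "dropout") {
      if (!is.null(ch$mask)) d <- d * ch$mask
    } else if (L$type == "flatten") {
      Vs <- prod(ch$dims)
      arr <- array(t(d), c(Vs, ch$C, N))       # (v, c, n)
      d <- matrix(aperm(arr, c(1, 3, 2)), Vs * N, ch$C)
    } else if (L$type == "pool") {
      Vs <- prod(L$dims)
      P2 <- prod(L$dims_out)
      dA <- matrix(0, Vs * N, ch$C)
      for (p in seq_len(8L)) {
        sel <- which(ch$arg == p, arr.ind = TRUE)
        if (!nrow(sel)) next
        u <- (sel[, 1] - 1L) %% P2 + 1L
        n <- (sel[, 1] - 1L) %/% P2 + 1L
        src <- L$idx8[u, p] + (n - 1L) * Vs
        dA[cbind(src, sel[, 2])] <- dA[cbind(src, sel[, 2])] + d[sel]
      }
      d <- dA
    } else if (L$type == "relu_conv") {
      d <- d * ch$mask
    } else if (L$type == "conv") {
      if (need_param_grads)
        grads[[li]] <- list(W = crossprod(ch$M, d), b = colSums(d))
      if (li > 1 || need_input_grad) {
        Vs <- prod(L$dims)
        Pg <- pad_batch(d, L$dims, L$C_out, N, L$interior)
        Mg <- gather_patches(Pg, L$grad_idx$idxC, Vs, N)
        d <- Mg %*% flip_kernel(L$W, L$C_in, L$C_out)
      }
    }
  }
  d_input <- NULL
  if (need_input_grad) {
    V <- prod(model$input_shape)
    d_input <- t(matrix(d, V, N))
  }
  list(grads = grads, d_stop = NULL, d_input = d_input)
}
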