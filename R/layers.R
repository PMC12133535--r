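# Layer environments hold parameters (W, b, gamma, beta, w), their
# gradient accumulators (gW, gb, ...), and optimizer state. Environments
# give reference semantics so the tape can accumulate gradients in place.

new_conv_layer <- function(kh, kw, cin, cout, bias = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  fan_in <- kh * kw * cin
  # He initialization for ReLU networks
  ly$W <- array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
                c(kh, kw, cin, cout))
  ly$b <- if (bias) numeric(cout) else NULL
  zero_grads(ly)
  ly
}

new_bn_layer <- function(C, eps = 1e-5, momentum = 0.1) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"
  ly$gamma <- rep(1, C)
  ly$beta <- numeric(C)
  ly$rmean <- numeric(C)
  ly$rvar <- rep(1, C)
  ly$eps <- eps
  ly$momentum <- momentum
  zero_grads(ly)
  ly
}

new_eca_layer <- function(C, gamma = 2, b = 1) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "eca"
  ly$k <- eca_kernel_size(C, gamma, b)
  ly$C <- C
  # small init so attention starts near the neutral 0.5 scaling
  ly$w <- stats::rnorm(ly$k, 0, 0.1)
  zero_grads(ly)
  ly
}

zero_grads <- function(ly) {
  switch(ly$type,
    conv = {
      if (!is.null(ly$W)) ly$gW <- array(0, dim(ly$W))
      if (!is.null(ly$b)) ly$gb <- numeric(length(ly$b))
    },
    bn = {
      ly$ggamma <- numeric(length(ly$gamma))
      ly$gbeta <- numeric(length(ly$beta))
    },
    eca = ly$gw <- numeric(length(ly$w))
  )
  invisible(ly)
}

# names of parameter fields and whether weight decay applies to each
layer_param_fields <- function(ly) {
  switch(ly$type,
    conv = {
      f <- c(W = TRUE)
      if (!is.null(ly$b)) f <- c(f, b = FALSE)
      f
    },
    bn = c(gamma = FALSE, beta = FALSE),
    eca = c(w = TRUE)
  )
}

grad_field <- function(field) paste0("g", field)

#' @noRd
model_layers <- function(model) model$layers

# One decoupled-weight-decay Adam step over every parameter tensor.
adamw_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  for (ly in layers) {
    fields <- layer_param_fields(ly)
    if (is.null(ly$.adam)) ly$.adam <- list()
    ly$.t <- if (is.null(ly$.t)) 1L else ly$.t + 1L
    t <- ly$.t
    for (f in names(fields)) {
      g <- ly[[grad_field(f)]]
      st <- ly$.adam[[f]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      if (fields[[f]]) upd <- upd + weight_decay * ly[[f]]
      ly[[f]] <- ly[[f]] - lr * upd
      ly$.adam[[f]] <- st
    }
    zero_grads(ly)
  }
  invisible(NULL)
}

# deep copy / restore of all parameters and batch-norm statistics
snapshot_params <- function(layers) {
  lapply(layers, function(ly) {
    switch(ly$type,
      conv = list(W = ly$W, b = ly$b),
      bn = list(gamma = ly$gamma, beta = ly$beta,
                rmean = ly$rmean, rvar = ly$rvar),
      eca = list(w = ly$w)
    )
  })
}

restore_params <- function(layers, snap) {
  stopifnot(length(layers) == length(snap))
  for (i in seq_along(layers)) {
    for (f in names(snap[[i]])) {
      if (!is.null(snap[[i]][[f]])) layers[[i]][[f]] <- snap[[i]][[f]]
    }
  }
  invisible(NULL)
}
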