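# Minimal CNN machinery on top of the src/ convolution kernels. Tensors are
# R arrays dim (H, W, C); conv weights are arrays dim (k, k, Cin, Cout).
# Everything is deterministic given the R RNG state at initialisation.

as_cube <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  x
}

conv_fwd <- function(x, w, b) {
  k <- dim(w)[1]; cout <- dim(w)[4]
  wf <- array(w, c(k * k * dim(w)[3], cout, 1))
  cpp_conv2d_fwd(as_cube(x), wf, b, k, cout)
}

conv_bwd <- function(x, w, gout) {
  k <- dim(w)[1]; cout <- dim(w)[4]
  wf <- array(w, c(k * k * dim(w)[3], cout, 1))
  r <- cpp_conv2d_bwd(as_cube(x), wf, as_cube(gout), k)
  r$gw <- array(r$gw, dim(w))
  r$gb <- as.vector(r$gb)
  r
}

relu <- function(x) pmax(x, 0)
relu_bwd <- function(x, gout) gout * (x > 0)

# He-scaled initialisation for one conv layer
init_conv <- function(k, cin, cout) {
  list(
    w = array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              c(k, k, cin, cout)),
    b = rep(0, cout)
  )
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# Adam over a flat named list of parameter arrays
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# flatten/unflatten nested parameter lists (layers -> w/b) for the optimiser
flatten_params <- function(layers) {
  out <- list()
  for (ln in names(layers)) {
    out[[paste0(ln, ".w")]] <- layers[[ln]]$w
    out[[paste0(ln, ".b")]] <- layers[[ln]]$b
  }
  out
}

unflatten_params <- function(flat) {
  layer_names <- unique(sub("\\.(w|b)$", "", names(flat)))
  setNames(lapply(layer_names, function(ln) {
    list(w = flat[[paste0(ln, ".w")]], b = flat[[paste0(ln, ".b")]])
  }), layer_names)
}
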