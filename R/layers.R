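# Module infrastructure: a module is an environment with named parameter
# tensors, named child modules and a forward closure. Parameters are
# collected recursively for the optimizer and for (de)serialization.

new_module <- function(type = "module") {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$children <- list()
  class(e) <- "nodseg_module"
  e
}

mod_param <- function(mod, name, value) {
  t <- ag_param(value)
  mod$params[[name]] <- t
  t
}

mod_child <- function(mod, name, child) {
  mod$children[[name]] <- child
  child
}

collect_params <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) {
    out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  }
  for (nm in names(mod$children)) {
    out <- c(out, collect_params(mod$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

n_params <- function(mod) {
  sum(vapply(collect_params(mod), function(p) length(p$v), numeric(1)))
}

# He-normal initialization for convolution kernels
he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

# Convolution layer; `bias = FALSE` whenever batch normalization follows
# (the BN shift makes a bias redundant and gradient-free).
layer_conv <- function(kh, kw, cin, cout, stride = 1L, ph = (kh - 1L) %/% 2L,
                       pw = (kw - 1L) %/% 2L, bias = TRUE) {
  m <- new_module("conv")
  mod_param(m, "w", he_init(kh, kw, cin, cout))
  if (bias) mod_param(m, "b", numeric(cout))
  m$fw <- function(x, training = FALSE) {
    op_conv2d(x, m$params$w, stride = stride, ph = ph, pw = pw, b = m$params$b)
  }
  m
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  m <- new_module("batchnorm")
  mod_param(m, "gamma", rep(1, c))
  mod_param(m, "beta", numeric(c))
  m$running_mean <- numeric(c)
  m$running_var <- rep(1, c)
  m$momentum <- momentum
  m$eps <- eps
  m$fw <- function(x, training = FALSE) {
    op_batchnorm(x, m$params$gamma, m$params$beta, m, training)
  }
  m
}

# 2x transposed convolution (kernel 2, stride 2)
layer_convT2 <- function(cin, cout, bias = TRUE) {
  m <- new_module("convT")
  mod_param(m, "w", he_init(2L, 2L, cout, cin))
  if (bias) mod_param(m, "b", numeric(cout))
  m$fw <- function(x, training = FALSE) op_convT2(x, m$params$w, b = m$params$b)
  m
}

layer_dense <- function(cin, cout, bias = TRUE) {
  m <- new_module("dense")
  mod_param(m, "w", matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin))
  if (bias) mod_param(m, "b", numeric(cout))
  m$fw <- function(x, training = FALSE) op_dense(m$params$w, x, b = m$params$b)
  m
}

# conv -> BN -> activation, the standard unit of the encoders
layer_cba <- function(kh, kw, cin, cout, act, stride = 1L) {
  m <- new_module("cba")
  mod_child(m, "conv", layer_conv(kh, kw, cin, cout, stride = stride, bias = FALSE))
  mod_child(m, "bn", layer_bn(cout))
  m$fw <- function(x, training = FALSE) {
    op_act(m$children$bn$fw(m$children$conv$fw(x, training), training), act)
  }
  m
}

# Serialize / restore parameter values and BN running statistics.
module_state <- function(mod, prefix = "") {
  st <- list()
  for (nm in names(mod$params)) st[[paste0(prefix, nm)]] <- mod$params[[nm]]$v
  if (mod$type == "batchnorm") {
    st[[paste0(prefix, ".running_mean")]] <- mod$running_mean
    st[[paste0(prefix, ".running_var")]] <- mod$running_var
  }
  for (nm in names(mod$children)) {
    st <- c(st, module_state(mod$children[[nm]], paste0(prefix, nm, ".")))
  }
  st
}

module_load_state <- function(mod, st, prefix = "") {
  for (nm in names(mod$params)) {
    key <- paste0(prefix, nm)
    if (is.null(st[[key]])) stop("missing parameter in state: ", key)
    v <- st[[key]]
    if (!is.null(dim(mod$params[[nm]]$v))) dim(v) <- dim(mod$params[[nm]]$v)
    mod$params[[nm]]$v <- v
  }
  if (mod$type == "batchnorm") {
    mod$running_mean <- as.numeric(st[[paste0(prefix, ".running_mean")]])
    mod$running_var <- as.numeric(st[[paste0(prefix, ".running_var")]])
  }
  for (nm in names(mod$children)) {
    module_load_state(mod$children[[nm]], st, paste0(prefix, nm, "."))
  }
  invisible(mod)
}
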