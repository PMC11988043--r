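## Layer constructors. A layer/module is a plain list whose ag_tensor elements
## (recursively) are its parameters; `nn_params()` walks any module tree.
## Forward application is explicit (`conv_apply()` etc.) so the network graphs
## in blocks.R / model.R read like the equations they implement.

he_sd <- function(fan_in) sqrt(2 / fan_in)

nn_init <- function(dims, sd) {
  array(stats::rnorm(prod(dims), 0, sd), dims)
}

#' Convolution layer constructor
#' @param cin,cout channel counts; `groups = cin` with `cout = cin` is depthwise.
#' @param k kernel size; `pad` defaults to "same" for stride 1.
#' @keywords internal
nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k %/% 2L) * dilation,
                    dilation = 1L, groups = 1L, bias = TRUE, name = "conv") {
  cg <- cin %/% groups
  w <- ag_tensor(nn_init(c(k, k, cg, cout), he_sd(k * k * cg)),
                 requires_grad = TRUE, name = paste0(name, ".w"))
  w$decay <- TRUE
  b <- if (bias) ag_tensor(numeric(cout), requires_grad = TRUE,
                           name = paste0(name, ".b")) else NULL
  list(kind = "conv", w = w, b = b, stride = stride, pad = pad,
       dilation = dilation, groups = groups)
}

conv_apply <- function(m, x) {
  ag_conv2d(x, m$w, m$b, stride = m$stride, pad = m$pad,
            dilation = m$dilation, groups = m$groups)
}

#' Depthwise-separable 3x3 convolution (depthwise then 1x1 pointwise).
#' @keywords internal
nn_dsconv <- function(cin, cout, stride = 1L, name = "dsconv") {
  list(kind = "dsconv",
       dw = nn_conv(cin, cin, k = 3L, stride = stride, groups = cin,
                    name = paste0(name, ".dw")),
       pw = nn_conv(cin, cout, k = 1L, name = paste0(name, ".pw")))
}

dsconv_apply <- function(m, x) conv_apply(m$pw, conv_apply(m$dw, x))

#' @keywords internal
nn_linear <- function(fin, fout, name = "fc") {
  w <- ag_tensor(nn_init(c(fout, fin), he_sd(fin)),
                 requires_grad = TRUE, name = paste0(name, ".w"))
  w$decay <- TRUE
  b <- ag_tensor(numeric(fout), requires_grad = TRUE, name = paste0(name, ".b"))
  list(kind = "linear", w = w, b = b)
}

linear_apply <- function(m, x) ag_linear(x, m$w, m$b)

#' Inverted-residual block: 1x1 expand, 3x3 depthwise (optionally strided),
#' 1x1 project; identity skip when the shape is preserved.
#' @keywords internal
nn_invres <- function(cin, cout, stride = 1L, expansion = 3, name = "block") {
  cmid <- max(4L, as.integer(round(cin * expansion)))
  list(kind = "invres",
       expand = nn_conv(cin, cmid, k = 1L, name = paste0(name, ".exp")),
       dw = nn_conv(cmid, cmid, k = 3L, stride = stride, groups = cmid,
                    name = paste0(name, ".dw")),
       project = nn_conv(cmid, cout, k = 1L, name = paste0(name, ".proj")),
       skip = (stride == 1L && cin == cout))
}

invres_apply <- function(m, x) {
  h <- ag_relu(conv_apply(m$expand, x))
  h <- ag_relu(conv_apply(m$dw, h))
  h <- conv_apply(m$project, h)
  if (m$skip) ag_add(h, x) else h
}

#' Collect the unique trainable parameters of a module tree
#'
#' Walks nested lists and returns every `ag_tensor` with `requires_grad`,
#' de-duplicated by identity so weight-shared stages are counted once.
#' @param module nested list of layers.
#' @return list of `ag_tensor` parameters.
#' @export
nn_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ag_tensor")) {
      if (x$requires_grad) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  ## de-duplicate by tensor id (shared stages appear twice in the tree)
  keep <- !duplicated(vapply(out, function(p) p$id, integer(1)))
  out[keep]
}

#' Total number of scalar trainable parameters in a module tree
#' @inheritParams nn_params
#' @export
nn_count_params <- function(module) {
  sum(vapply(nn_params(module), function(p) length(p$v), numeric(1)))
}

## flat named list of parameter values (for checkpoints)
nn_state <- function(module) {
  ps <- nn_params(module)
  nm <- vapply(ps, function(p) p$name %||% "param", "")
  nm <- make.unique(nm, sep = "#")
  stats::setNames(lapply(ps, function(p) p$v), nm)
}

nn_load_state <- function(module, state) {
  ps <- nn_params(module)
  nm <- make.unique(vapply(ps, function(p) p$name %||% "param", ""), sep = "#")
  for (i in seq_along(ps)) {
    v <- state[[nm[i]]]
    if (is.null(v) || length(v) != length(ps[[i]]$v))
      stop("checkpoint incompatible with model at parameter ", nm[i])
    dim(v) <- dim(ps[[i]]$v)
    ps[[i]]$v <- v
  }
  invisible(module)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
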