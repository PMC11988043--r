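## Reverse-mode autodiff core.
##
## A tensor is an environment holding a value `v` (numeric array), an optional
## accumulated gradient `g`, and, for non-leaf nodes, a backward closure `bw`
## that routes the node's gradient to its parents. Operations executed while a
## tape is active append their output nodes to the tape; `ag_backward()` seeds
## the loss gradient and replays the tape in reverse.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L
.ag$id <- 0L

#' Create an autodiff tensor
#'
#' Wraps a numeric array as a node of the computation graph. Leaf tensors with
#' `requires_grad = TRUE` are trainable parameters: gradients accumulate in
#' `$g` across a forward/backward pass until [ag_zero_grad()].
#'
#' @param v numeric array (any dimensionality; network activations use
#'   `c(H, W, C, N)` layout).
#' @param requires_grad accumulate gradients into this leaf?
#' @param name optional label (used in checkpoints and error messages).
#' @return an object of class `ag_tensor`.
#' @keywords internal
ag_tensor <- function(v, requires_grad = FALSE, name = NULL) {
  t <- new.env(parent = emptyenv())
  t$v <- v
  t$g <- NULL
  t$requires_grad <- requires_grad
  t$needs <- requires_grad
  t$bw <- NULL
  t$name <- name
  t$decay <- FALSE
  .ag$id <- .ag$id + 1L
  t$id <- .ag$id
  class(t) <- "ag_tensor"
  t
}

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<ag_tensor", if (!is.null(x$name)) x$name else "",
      if (is.null(d)) paste0("len=", length(x$v)) else paste(d, collapse = "x"),
      if (x$requires_grad) "(param)" else "", ">\n")
  invisible(x)
}

ag_tape_begin <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_tape_end <- function() {
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_push <- function(t) {
  if (!is.null(.ag$tape)) {
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- t
    .ag$n <- n
  }
  t
}

## create an op output node; bw is function(g) performing parent accumulation
ag_node <- function(v, parents, bw) {
  needs <- FALSE
  for (p in parents) if (p$needs) { needs <- TRUE; break }
  t <- ag_tensor(v)
  t$needs <- needs
  if (needs) t$bw <- bw
  ag_push(t)
}

ag_acc <- function(t, g) {
  if (!t$needs) return(invisible(NULL))
  if (is.null(t$g)) t$g <- g else t$g <- t$g + g
  invisible(NULL)
}

#' Run reverse-mode backpropagation from a scalar loss node
#'
#' Seeds the loss gradient with 1 and replays the active tape in reverse
#' creation order, accumulating gradients into every node that (transitively)
#' depends on a trainable parameter. The tape is released afterwards.
#' @param loss scalar `ag_tensor` produced under an active tape.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(inherits(loss, "ag_tensor"), length(loss$v) == 1L)
  if (is.null(.ag$tape)) stop("ag_backward: no active tape")
  loss$g <- if (is.null(dim(loss$v))) 1 else array(1, dim(loss$v))
  for (i in seq.int(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  ag_tape_end()
  invisible(NULL)
}

#' Clear accumulated gradients on a list of parameters
#' @param params list of `ag_tensor`
#' @keywords internal
ag_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

## Evaluate an expression under a fresh tape, guaranteeing release.
with_tape <- function(expr) {
  ag_tape_begin()
  on.exit(ag_tape_end(), add = TRUE)
  expr
}
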