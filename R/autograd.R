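# Minimal reverse-mode automatic differentiation.
#
# A tensor node is an environment holding $value (a numeric array), an
# optional $grad, the $parents it was computed from and a $backward
# closure mapping the node's gradient to a list of parent gradients
# (positionally aligned with $parents).  Graph recording is gated by a
# package-level switch so that inference runs on plain arrays with no
# bookkeeping.

.afn <- new.env(parent = emptyenv())
.afn$grad_enabled <- FALSE

#' Enable or disable gradient recording
#'
#' While recording is enabled, tensor operations build a computation
#' graph that [ag_backward()] can traverse.  With recording disabled
#' (the default) every operation returns a plain numeric array.
#'
#' @param on logical switch.
#' @return the previous state, invisibly.
#' @keywords internal
#' @export
ag_grad_enabled <- function(on) {
  old <- .afn$grad_enabled
  .afn$grad_enabled <- isTRUE(on)
  invisible(old)
}

#' Run an expression with gradient recording switched on
#' @param expr expression to evaluate.
#' @keywords internal
#' @export
with_grad <- function(expr) {
  old <- ag_grad_enabled(TRUE)
  on.exit(ag_grad_enabled(old))
  expr
}

grad_on <- function() .afn$grad_enabled

#' Create a tensor node
#'
#' @param value numeric array.
#' @param parents list of parent nodes (may include plain arrays).
#' @param backward function(grad) returning a list of parent gradients.
#' @param name optional label used in checkpoints and error messages.
#' @keywords internal
#' @export
ag_tensor <- function(value, parents = list(), backward = NULL, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- TRUE
  e$grad <- NULL
  e$name <- name
  e$.seen <- FALSE
  class(e) <- "ag_tensor"
  e
}

#' Create a leaf tensor (a trainable parameter or a tracked input)
#' @inheritParams ag_tensor
#' @keywords internal
#' @export
ag_leaf <- function(value, name = NULL) ag_tensor(value, name = name)

is_ag <- function(x) inherits(x, "ag_tensor")

#' Extract the numeric value of a tensor node or pass a plain array through
#' @param x tensor node or numeric array.
#' @keywords internal
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (!is.null(x$name)) x$name else "",
      if (is.null(d)) paste0("len ", length(x$value)) else paste(d, collapse = "x"),
      if (is.null(x$backward) && length(x$parents) == 0L) "(leaf)" else "",
      ">\n")
  invisible(x)
}

# Build an op node when recording, otherwise return the plain value.
ag_op <- function(value, parents, backward) {
  if (!grad_on() || !any(vapply(parents, is_ag, logical(1L))))
    return(value)
  ag_tensor(value, parents = parents, backward = backward)
}

#' Backpropagate gradients from a (scalar) root node
#'
#' Performs a depth-first topological sort of the recorded graph and
#' accumulates gradients into every reachable node; leaf nodes keep their
#' `$grad` afterwards.
#'
#' @param root tensor node to differentiate.
#' @param grad seed gradient (defaults to 1, i.e. a scalar root).
#' @keywords internal
#' @export
ag_backward <- function(root, grad = NULL) {
  stopifnot(is_ag(root))
  topo <- vector("list", 64L)
  k <- 0L
  visit <- function(n) {
    if (n$.seen) return(invisible(NULL))
    n$.seen <- TRUE
    for (p in n$parents) if (is_ag(p)) visit(p)
    k <<- k + 1L
    if (k > length(topo)) length(topo) <<- 2L * k
    topo[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  topo <- topo[seq_len(k)]
  for (n in topo) {
    n$.seen <- FALSE
    if (!identical(n, root)) n$grad <- NULL
  }
  if (is.null(grad)) {
    grad <- root$value
    grad[] <- 1
  }
  root$grad <- grad
  for (n in rev(topo)) {
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    ps <- n$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!is_ag(p)) next
      g <- gs[[i]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (length(n$parents) > 0L) n$grad <- NULL  # free non-leaf grads
  }
  invisible(root)
}

#' Zero the gradients of a list of leaf tensors
#' @param params list of tensor nodes.
#' @keywords internal
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
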