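# Minimal reverse-mode tape used by the 3D network engine.
#
# A "tracked tensor" is list(id, v): `id` indexes a node on the tape and `v`
# is a plain numeric array. Ops append one node each; node$backward maps the
# gradient at the node's output to gradients for its parents (by position)
# and for any named parameters it consumed. With tape = NULL the ops compute
# values only, which is the inference path.

tp_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$n <- 0L
  e
}

tp_leaf <- function(tape, v) {
  if (is.null(tape)) return(list(id = 0L, v = v))
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- list(parents = integer(0), backward = NULL)
  list(id = tape$n, v = v)
}

tp_node <- function(tape, v, parents, backward) {
  if (is.null(tape)) return(list(id = 0L, v = v))
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- list(parents = as.integer(parents), backward = backward)
  list(id = tape$n, v = v)
}

# Walk the tape in reverse from `out`, seeding with `gout` (same shape as
# out$v). Returns the named list of parameter gradients, accumulated across
# all nodes that consumed each parameter.
tp_backward <- function(tape, out, gout) {
  grads <- vector("list", tape$n)
  grads[[out$id]] <- gout
  wg <- list()
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    g <- grads[[i]]
    grads[i] <- list(NULL)
    if (is.null(g) || is.null(nd$backward)) next
    res <- nd$backward(g)
    ps <- nd$parents
    if (length(ps)) {
      for (j in seq_along(ps)) {
        pg <- res$pgrads[[j]]
        if (is.null(pg)) next
        p <- ps[j]
        grads[[p]] <- if (is.null(grads[[p]])) pg else grads[[p]] + pg
      }
    }
    if (!is.null(res$wgrads)) {
      for (nm in names(res$wgrads)) {
        wg[[nm]] <- if (is.null(wg[[nm]])) res$wgrads[[nm]] else wg[[nm]] + res$wgrads[[nm]]
      }
    }
    tape$nodes[i] <- list(NULL)
  }
  wg
}
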