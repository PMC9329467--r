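# Optimizers over lists of parameter leaf nodes. Parameters persist across
# steps; each step consumes and clears the gradients accumulated by
# ag_backward().

opt_adam <- function(params, lr = 1e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$value * 0)   # zero, same shape/attrs
  st$v <- st$m
  st$t <- 0L
  list(
    step = function() {
      st$t <- st$t + 1L
      bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
      for (i in seq_along(params)) {
        p <- params[[i]]
        if (is.null(p$grad)) next
        g <- p$grad
        st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
        st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g^2
        p$value <- p$value - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
        p$grad <- NULL
      }
    },
    zero = function() for (p in params) p$grad <- NULL
  )
}

opt_sgd <- function(params, lr = 1e-4) {
  list(
    step = function() {
      for (p in params) {
        if (is.null(p$grad)) next
        p$value <- p$value - lr * p$grad
        p$grad <- NULL
      }
    },
    zero = function() for (p in params) p$grad <- NULL
  )
}
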