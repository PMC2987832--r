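#' @title Strand-symmetric context-dependent substitution models
#' @name context_model
NULL

# ---- rate-class bookkeeping ---------------------------------------------
#
# A model assigns a rate to every (left, center -> alt, right) substitution,
# tied under strand symmetry: rate(l, x->y, r) = rate(comp(r), comp(x)->comp(y), comp(l)).
# Two parameterizations are supported:
#   "u3s": full trinucleotide context; contexts (l,r) give 16 "qclasses" and
#          the 192 context-substitutions collapse to 96 symmetry orbits.
#   "cpg": reduced CpG-aware model with 4 rate classes (ts, tv, deam, gain);
#          only the predicates left==C and right==G matter, so the 16 flank
#          contexts collapse to 4 rate-distinct qclasses.

.icrevo_cache <- new.env(parent = emptyenv())

# substitution category with respect to CpG creation/destruction, used both
# for the reduced model's classes and for rate summaries
sub_flags <- function(l, x, y, r) {
  transition <- (x + y) %in% c(4L, 6L) && x != y # A<->G (1,3), C<->T (2,4)
  n_before <- (l == 2L && x == 3L) + (x == 2L && r == 3L)
  n_after <- (l == 2L && y == 3L) + (y == 2L && r == 3L)
  deam <- (x == 2L && y == 4L && r == 3L) || (x == 3L && y == 1L && l == 2L)
  gain_tpg <- (x == 4L && y == 2L && r == 3L) || (x == 1L && y == 3L && l == 2L)
  list(
    transition = transition,
    loss_deam = deam,
    loss_any = n_after < n_before,
    gain_tpg = gain_tpg,
    gain_any = n_after > n_before,
    neutral_cpg = n_after == n_before
  )
}

class_tables <- function(type = c("cpg", "u3s")) {
  type <- match.arg(type)
  key <- paste0("ct_", type)
  if (!is.null(.icrevo_cache[[key]])) return(.icrevo_cache[[key]])
  if (type == "cpg") {
    n_qclass <- 4L
    qidx <- matrix(0L, 4, 4) # [l, r] -> qclass
    for (l in 1:4) for (r in 1:4) {
      qidx[l, r] <- 1L + (l == 2L) + 2L * (r == 3L)
    }
    # representative (l, r) per qclass for flag computation
    reps <- list(c(1L, 1L), c(2L, 1L), c(1L, 3L), c(2L, 3L))
    cmap <- array(0L, c(n_qclass, 4, 4))
    for (q in 1:n_qclass) {
      l <- reps[[q]][1]; r <- reps[[q]][2]
      for (x in 1:4) for (y in 1:4) {
        if (x == y) next
        fl <- sub_flags(l, x, y, r)
        cmap[q, x, y] <- if (fl$loss_deam) 3L else if (fl$gain_tpg) 4L
          else if (fl$transition) 1L else 2L
      }
    }
    class_names <- c("ts", "tv", "deam", "gain")
    out <- list(type = type, n_qclass = n_qclass, n_class = 4L,
                qidx = qidx, qreps = reps, cmap = cmap, class_names = class_names)
  } else {
    n_qclass <- 16L
    qidx <- matrix(0L, 4, 4)
    for (l in 1:4) for (r in 1:4) qidx[l, r] <- (l - 1L) * 4L + r
    reps <- vector("list", 16L)
    for (l in 1:4) for (r in 1:4) reps[[(l - 1L) * 4L + r]] <- c(l, r)
    # orbit ids of (l, x, y, r) under the strand-symmetry mirror
    orbit <- array(0L, c(4, 4, 4, 4)) # [l, x, y, r]
    nid <- 0L
    for (l in 1:4) for (x in 1:4) for (y in 1:4) for (r in 1:4) {
      if (x == y) next
      if (orbit[l, x, y, r] > 0L) next
      nid <- nid + 1L
      orbit[l, x, y, r] <- nid
      m <- c(COMP[r], COMP[x], COMP[y], COMP[l])
      orbit[m[1], m[2], m[3], m[4]] <- nid
    }
    cmap <- array(0L, c(n_qclass, 4, 4))
    for (q in 1:n_qclass) {
      l <- reps[[q]][1]; r <- reps[[q]][2]
      for (x in 1:4) for (y in 1:4) {
        if (x != y) cmap[q, x, y] <- orbit[l, x, y, r]
      }
    }
    class_names <- character(nid)
    for (l in 1:4) for (x in 1:4) for (y in 1:4) for (r in 1:4) {
      if (x == y) next
      id <- orbit[l, x, y, r]
      if (!nzchar(class_names[id])) {
        class_names[id] <- sprintf("%s[%s>%s]%s", BASES[l], BASES[x], BASES[y], BASES[r])
      }
    }
    out <- list(type = type, n_qclass = n_qclass, n_class = nid,
                qidx = qidx, qreps = reps, cmap = cmap, class_names = class_names,
                orbit = orbit)
  }
  .icrevo_cache[[key]] <- out
  out
}

# flags per (qclass, x, y) for rate summaries, as a data.frame
qclass_flags <- function(tables) {
  key <- paste0("fl_", tables$type)
  if (!is.null(.icrevo_cache[[key]])) return(.icrevo_cache[[key]])
  rows <- list()
  for (q in seq_len(tables$n_qclass)) {
    l <- tables$qreps[[q]][1]; r <- tables$qreps[[q]][2]
    for (x in 1:4) for (y in 1:4) {
      if (x == y) next
      fl <- sub_flags(l, x, y, r)
      rows[[length(rows) + 1L]] <- data.frame(
        qclass = q, from = x, to = y, class = tables$cmap[q, x, y],
        transition = fl$transition, loss_deam = fl$loss_deam,
        loss_any = fl$loss_any, gain_tpg = fl$gain_tpg, gain_any = fl$gain_any,
        neutral_cpg = fl$neutral_cpg
      )
    }
  }
  out <- do.call(rbind, rows)
  .icrevo_cache[[key]] <- out
  out
}

# ---- model constructors --------------------------------------------------

new_context_model <- function(type, rates, root_comp) {
  tables <- class_tables(type)
  stopifnot(length(rates) == tables$n_class,
            all(is.na(rates) | rates >= 0)) # NA marks a degenerate fit
  names(rates) <- tables$class_names
  structure(
    list(type = type, rates = rates, root_comp = root_comp),
    class = "context_model"
  )
}

#' Reduced CpG-aware context model
#'
#' A four-parameter strand-symmetric model: a baseline transition rate, a
#' transversion rate, a CpG-deamination rate applied to C->T with a G on the
#' right (and, by strand symmetry, G->A with a C on the left), and a CpG-gain
#' rate applied to the TpG->CpG / CpA->CpG transitions. Rates are relative;
#' only ratios and the branch-length scale matter.
#'
#' @param ts,tv,deam,gain non-negative rates. The defaults place CpG
#'   deamination tenfold above the baseline transition rate, the elevation
#'   classically reported for methylated CpG sites.
#' @param root_comp trinucleotide root composition (see [trinuc_composition()]).
#' @return a `context_model` object.
#' @export
cpg_context_model <- function(ts = 1, tv = 0.25, deam = 10, gain = 2,
                              root_comp = trinuc_composition()) {
  new_context_model("cpg", c(ts, tv, deam, gain), root_comp)
}

#' Full strand-symmetric trinucleotide context model (U3S)
#'
#' One free rate per strand-symmetry orbit of (left, center->alt, right)
#' substitutions (96 orbits).
#'
#' @param rates numeric vector of length 96 (orbit order as in
#'   `class_tables("u3s")$class_names`), or a single number used for all
#'   orbits.
#' @param root_comp trinucleotide root composition.
#' @return a `context_model` object.
#' @export
u3s_context_model <- function(rates = 1, root_comp = trinuc_composition()) {
  tables <- class_tables("u3s")
  if (length(rates) == 1L) rates <- rep(rates, tables$n_class)
  new_context_model("u3s", rates, root_comp)
}

#' Convert a context model to a U3S parameterization
#'
#' Expands the rate classes of any model to the 96 strand-symmetry orbits.
#' @param model a `context_model`.
#' @return a `context_model` of type `"u3s"`.
#' @export
as_u3s <- function(model) {
  stopifnot(inherits(model, "context_model"))
  if (model$type == "u3s") return(model)
  arr <- rate_array(model)
  t3 <- class_tables("u3s")
  rates <- numeric(t3$n_class)
  for (l in 1:4) for (x in 1:4) for (y in 1:4) for (r in 1:4) {
    if (x == y) next
    rates[t3$orbit[l, x, y, r]] <- arr[l, x, r, y]
  }
  new_context_model("u3s", rates, model$root_comp)
}

#' Full rate lookup array of a context model
#'
#' @param model a `context_model`.
#' @return a 4x4x4x4 array indexed `[left, center, right, alt]` of rates,
#'   zero on the diagonal (alt == center).
#' @export
rate_array <- function(model) {
  stopifnot(inherits(model, "context_model"))
  tables <- class_tables(model$type)
  arr <- array(0, c(4, 4, 4, 4))
  for (l in 1:4) for (r in 1:4) {
    q <- tables$qidx[l, r]
    for (x in 1:4) for (y in 1:4) {
      if (x == y) next
      arr[l, x, r, y] <- model$rates[tables$cmap[q, x, y]]
    }
  }
  arr
}

#' Check strand symmetry of a rate array
#'
#' @param arr a 4x4x4x4 rate array as returned by [rate_array()].
#' @return TRUE if `arr[l,x,r,y] == arr[comp(r),comp(x),comp(l),comp(y)]`
#'   for all entries, exactly.
#' @export
is_strand_symmetric <- function(arr) {
  for (l in 1:4) for (x in 1:4) for (r in 1:4) for (y in 1:4) {
    if (arr[l, x, r, y] != arr[COMP[r], COMP[x], COMP[l], COMP[y]]) return(FALSE)
  }
  TRUE
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf("Strand-symmetric context-dependent model (%s), %d rate classes\n",
              x$type, length(x$rates)))
  if (x$type == "cpg") {
    cat(sprintf("  ts=%.4g tv=%.4g CpG-deamination=%.4g CpG-gain=%.4g\n",
                x$rates["ts"], x$rates["tv"], x$rates["deam"], x$rates["gain"]))
  } else {
    cat("  rate range:", sprintf("%.4g", range(x$rates)), "\n")
  }
  invisible(x)
}

# ---- root composition ----------------------------------------------------

#' Trinucleotide root composition
#'
#' Builds a trinucleotide probability array with a given GC fraction and CpG
#' observed/expected ratio: `f(a,b,c) \propto p(a) p(b) p(c) w(a,b) w(b,c)`
#' where `w` multiplies CG dinucleotides by `cpg_obs_exp`. Root sequences are
#' sampled from the implied second-order Markov chain, so the realized CpG
#' content of simulated roots tracks `cpg_obs_exp`.
#'
#' @param gc GC fraction of the base composition.
#' @param cpg_obs_exp target observed/expected CpG ratio.
#' @return a 4x4x4 probability array (sums to 1), class `trinuc_comp`.
#' @export
trinuc_composition <- function(gc = 0.5, cpg_obs_exp = 1) {
  stopifnot(gc > 0, gc < 1, cpg_obs_exp >= 0)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  f <- array(0, c(4, 4, 4))
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    w1 <- if (a == 2L && b == 3L) cpg_obs_exp else 1
    w2 <- if (b == 2L && c == 3L) cpg_obs_exp else 1
    f[a, b, c] <- p[a] * p[b] * p[c] * w1 * w2
  }
  structure(f / sum(f), class = "trinuc_comp")
}

# sample a root sequence of length n from the second-order chain implied by f
sample_root <- function(comp, n) {
  stopifnot(n >= 3)
  f <- unclass(comp)
  # marginal over (a, b)
  m2 <- apply(f, c(1, 2), sum)
  cond <- f
  for (a in 1:4) for (b in 1:4) {
    s <- sum(f[a, b, ])
    cond[a, b, ] <- if (s > 0) f[a, b, ] / s else rep(0.25, 4)
  }
  out <- integer(n)
  ab <- sample.int(16L, 1L, prob = as.vector(m2))
  out[1] <- ((ab - 1L) %% 4L) + 1L
  out[2] <- ((ab - 1L) %/% 4L) + 1L
  # m2 is [a, b]; as.vector is column-major: index = a + 4*(b-1)
  out[1] <- ((ab - 1L) %% 4L) + 1L
  out[2] <- ((ab - 1L) %/% 4L) + 1L
  u <- runif(n - 2L)
  for (i in 3:n) {
    pr <- cond[out[i - 2L], out[i - 1L], ]
    out[i] <- findInterval(u[i - 2L], cumsum(pr), left.open = TRUE) + 1L
    if (out[i] > 4L) out[i] <- 4L
  }
  out
}

codes_to_seq <- function(codes) {
  paste(c(BASES, "-")[ifelse(is.na(codes), 5L, codes)], collapse = "")
}
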