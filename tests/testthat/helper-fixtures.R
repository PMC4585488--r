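# shared test helpers: partition comparison, truth matching, tiny fixtures

# canonical form of a cell partition: sorted membership strings
partition_norm <- function(groups) {
  unname(sort(vapply(groups, function(v) paste(sort(v), collapse = ","),
                     character(1))))
}

truth_partition <- function(sim) split(sim$truth$cell_id, sim$truth$clone_id)

decoded_partition <- function(partition) {
  cl <- partition$cells$clone
  split(partition$cells$cell_id[!is.na(cl)], cl[!is.na(cl)])
}

# map detected cells to simulated cells by nearest centroid
match_to_truth <- function(det, cells) {
  dd <- outer(det$x_um, cells$x_um, "-")^2 + outer(det$y_um, cells$y_um, "-")^2
  apply(dd, 1L, which.min)
}

# independent brute-force Mann-Whitney p by enumeration over label assignments
brute_mann_whitney_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
    u
  }
  obs <- u_of(a, b)
  us <- apply(utils::combn(length(pooled), na), 2L,
              function(i) u_of(pooled[i], pooled[-i]))
  ge <- mean(us >= obs - 1e-12)
  le <- mean(us <= obs + 1e-12)
  switch(alternative,
         greater = ge, less = le,
         two.sided = min(1, 2 * min(ge, le)))
}

tiny_model <- function() {
  cortical_model(c(0, 100, 200), c("upper", "lower"), slab_width_um = 400)
}
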