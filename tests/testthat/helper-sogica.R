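# shared fixtures: everything is generated in code at test time

tiny_grid <- function(vox = 6) {
  make_grid(c(-30, 30), c(-30, 30), c(-30, 30), voxel_mm = vox)
}

# small two-network atlas for fast unit tests
tiny_networks <- function() {
  a <- network_spec("DMN", rbind(node_spec("A", "L", c(-12, 12, 0)),
                                 node_spec("B", "R", c(18, -12, 6))), 1L)
  b <- network_spec("SN", rbind(node_spec("C", "midline", c(0, 18, 12))), 2L)
  list(DMN = a, SN = b)
}

tiny_cfg <- function(...) {
  args <- list(n_EDp = 3, n_HC = 3, n_volumes = 40, voxel_mm = 6,
               master_seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# independent connected-component labeller (breadth-first, pure R);
# oracle for the compiled implementation
label_components_R <- function(arr, connectivity = 26) {
  d <- dim(arr)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  cur <- 0L
  for (s in which(arr & lab == 0L)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        j <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
        if (arr[j] && lab[j] == 0L) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  attr(lab, "n_components") <- cur
  lab
}
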