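# Shared fixtures built in code. Everything is generated at test time;
# seeds are fixed for reproducibility.

e3_spec <- function() archetype_defaults()$E3

simple_archetype <- function(gain = 0.25, rheo = 20) {
  archetype_spec("steady_regular", fi_gain = gain, fi_rheobase = rheo,
                 adaptation = 0.02, isi_cv = 0.05,
                 ap_width = 3.3, ap_amplitude = 55.2,
                 ap_threshold = -29.6, repol_duration = 2.4,
                 ahp_amplitude = 19.5, ahp_duration = 29.6)
}

single_boltzmann <- function(v50 = -28.18, slope = 8, gmax = 20,
                             reversal = -90) {
  conductance_spec(data.frame(gmax = gmax, v50 = v50, slope = slope,
                              tea_sensitive = TRUE,
                              dtx_sensitive = FALSE),
                   reversal = reversal)
}

# small three-node unbranched SWC written to a temp file
write_tiny_swc <- function(path = tempfile(fileext = ".swc")) {
  writeLines(c("# tiny fixture",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), path)
  path
}

# symmetric binary tree of given depth in the +x half plane; every
# branch splits into two; segment length shrinks with depth so circles
# between levels cut all branches of that level
symmetric_binary_tree <- function(depth, seg = 100) {
  nodes <- data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                      radius = 5, parent = -1)
  nid <- 1
  tips <- data.frame(id = 1, x = 0, y = 0, angle = 0)
  for (d in seq_len(depth)) {
    new_tips <- NULL
    for (r in seq_len(nrow(tips))) {
      for (s in c(-1, 1)) {
        ang <- tips$angle[r] + s * pi / (2^(d + 1))
        nid <- nid + 1
        x <- tips$x[r] + seg * cos(ang)
        y <- tips$y[r] + seg * sin(ang)
        nodes[nrow(nodes) + 1, ] <- list(nid, 3, x, y, 0, 0.5,
                                         tips$id[r])
        new_tips <- rbind(new_tips,
                          data.frame(id = nid, x = x, y = y,
                                     angle = ang))
      }
    }
    tips <- new_tips
  }
  morphology(nodes)
}

# brute-force Sholl oracle: sample points densely along every segment
# and count sign changes of (distance - r)
sholl_brute_force <- function(morph, radii, n_samp = 2000) {
  n <- morph$nodes
  soma <- n[n$id == morph$soma_id, ]
  pos <- match(n$parent, n$id)
  segs <- which(!is.na(pos))
  counts <- numeric(length(radii))
  for (s in segs) {
    p1 <- c(n$x[pos[s]], n$y[pos[s]])
    p2 <- c(n$x[s], n$y[s])
    u <- seq(0, 1, length.out = n_samp)
    d <- sqrt((p1[1] + u * (p2[1] - p1[1]) - soma$x)^2 +
                (p1[2] + u * (p2[2] - p1[2]) - soma$y)^2)
    for (i in seq_along(radii))
      counts[i] <- counts[i] + sum(abs(diff(sign(d - radii[i]))) > 0)
  }
  counts
}
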