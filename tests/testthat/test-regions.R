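## Site ids are row-major: on a 2 x 3 patch the first row is 1,2,3 and the
## second row 4,5,6 (the two-row worked example's x1,x2,x3 / x129,x130,x131).

region_set <- function(rg) {
  sort(vapply(rg$regions, paste, "", collapse = ","))
}

test_that("Bethe (d=2) region graph on the 2x3 patch has seven pairs and the right site corrections", {
  rg <- build_region_graph(c(2, 3), 2)
  cn <- counting_numbers(rg)
  pairs <- names(cn)[lengths(strsplit(names(cn), ",")) == 2]
  expect_setequal(pairs, c("1,2", "2,3", "4,5", "5,6", "1,4", "2,5", "3,6"))
  expect_true(all(cn[pairs] == 1))
  ## corner-column sites subtracted once, middle-column sites twice
  expect_equal(unname(cn[c("1", "3", "4", "6")]), rep(-1L, 4))
  expect_equal(unname(cn[c("2", "5")]), rep(-2L, 2))
})

test_that("B3 (d=3) region graph on the 2x3 patch matches the worked triangle decomposition", {
  rg <- build_region_graph(c(2, 3), 3)
  cn <- counting_numbers(rg)
  tris <- names(cn)[lengths(strsplit(names(cn), ",")) == 3]
  ## the four triangles S(x129,1,2), S(x129,130,2), S(x130,2,3), S(x130,131,3)
  expect_setequal(tris, c("1,2,4", "2,4,5", "2,3,5", "3,5,6"))
  expect_true(all(cn[tris] == 1))
  ## exactly three pairs subtracted: (x2,x129), (x3,x130), (x2,x130)
  pairs <- names(cn)[lengths(strsplit(names(cn), ",")) == 2]
  sub <- pairs[cn[pairs] != 0]
  expect_setequal(sub, c("2,4", "3,5", "2,5"))
  expect_true(all(cn[sub] == -1))
  ## no site terms survive on this patch
  sites <- names(cn)[lengths(strsplit(names(cn), ",")) == 1]
  expect_true(all(cn[sites] == 0))
})

test_that("counting numbers follow the Moebius rule on canonical cases", {
  ## d=1: isolated base regions, no super-regions
  rg1 <- build_region_graph(c(2, 2), 1)
  expect_true(all(counting_numbers(rg1) == 1))
  expect_equal(length(rg1$regions), 4L)
  ## a site in exactly three pairs gets 1 - 3 = -2 (checked above for x2);
  ## an anti-diagonal pair shared by exactly two triangles gets 1 - 2 = -1
  rg3 <- build_region_graph(c(2, 2), 3)
  cn <- counting_numbers(rg3)
  expect_equal(unname(cn[["2,3"]]), -1L)   # the shared hypotenuse
  ## full: a single region with c = 1
  rgf <- build_region_graph(c(3, 3), "full")
  expect_equal(length(rgf$regions), 1L)
  expect_equal(unname(counting_numbers(rgf)), 1L)
})

test_that("exact-counting condition holds at every site for all orders and shapes", {
  shapes <- list(c(2, 2), c(2, 3), c(3, 2), c(3, 3), c(3, 4), c(4, 4), c(2, 5))
  for (shape in shapes) {
    for (d in list(1, 2, 3)) {
      rg <- build_region_graph(shape, d)
      per_site <- numeric(prod(shape))
      for (k in seq_along(rg$regions)) {
        per_site[rg$regions[[k]]] <- per_site[rg$regions[[k]]] + rg$counting[k]
      }
      expect_equal(per_site, rep(1, prod(shape)),
                   info = sprintf("shape %dx%d d=%s", shape[1], shape[2], d))
    }
  }
})

test_that("closed-form class summaries agree with the explicit Moebius enumeration", {
  shapes <- list(c(2, 2), c(2, 3), c(3, 3), c(3, 4), c(4, 4), c(2, 5))
  for (shape in shapes) {
    for (d in list(1, 2, 3)) {
      rg <- build_region_graph(shape, d)
      agg <- tapply(rg$counting, rg$region_class, sum)
      cls <- region_classes(shape, d)
      for (k in seq_len(nrow(cls))) {
        got <- if (cls$class[k] %in% names(agg)) agg[[cls$class[k]]] else 0L
        expect_equal(got, cls$c_total[k],
                     info = sprintf("shape %dx%d d=%s class %s",
                                    shape[1], shape[2], d, cls$class[k]))
      }
      ## no shapes outside the catalogue appear
      expect_true(all(rg$region_class %in% cls$class))
    }
  }
})

test_that("Bethe counting numbers equal 1 - degree at every site", {
  rg <- build_region_graph(c(4, 5), 2)
  cn <- counting_numbers(rg)
  g <- make_grid(4, 5)
  for (i in 1:4) for (j in 1:5) {
    id <- (i - 1) * 5 + j
    deg <- nrow(neighbors4(g, c(i, j)))
    expect_equal(unname(cn[[as.character(id)]]), 1L - deg)
  }
})

test_that("unsupported orders and non-explicit graphs are rejected cleanly", {
  expect_error(build_region_graph(c(3, 3), 4), "order_d")
  expect_error(build_region_graph(c(1, 4), 2), "2 x 2")
  rg <- build_region_graph(c(8, 8), 3, explicit = FALSE)
  expect_error(counting_numbers(rg), "explicit")
})

test_that("region graph JSON dump round-trips the counting numbers", {
  rg <- build_region_graph(c(2, 3), 3)
  f <- tempfile(fileext = ".json")
  write_region_graph_json(rg, f)
  dumped <- jsonlite::read_json(f)
  expect_equal(length(dumped$regions), length(rg$regions))
  counting <- vapply(dumped$regions, function(r) r$counting, 1)
  expect_equal(counting, as.numeric(rg$counting))
  unlink(f)
})
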