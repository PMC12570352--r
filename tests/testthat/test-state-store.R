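# Dynamic-array containers: contiguity, stable slot ids, chain integrity and
# unbiased random selection, checked against naive shadow models.

test_that("dense array appends sequentially and grows by doubling", {
  a <- dense_array(capacity = 4L)
  idx <- vapply(c("a", "b", "c"), function(x) as.integer(dense_append(a, x)),
                integer(1))
  expect_equal(unname(idx), 1:3)
  expect_equal(length(a), 3L)
  dense_append(a, "d")
  expect_equal(a$cap, 4L)
  dense_append(a, "e")
  expect_equal(a$cap, 8L)   # multiplicative growth
  expect_equal(unlist(a$items[1:5]), c("a", "b", "c", "d", "e"))
})

test_that("dense delete pops and swaps, keeping the live region contiguous", {
  a <- dense_array()
  ids <- vapply(c("a", "b", "c"), function(x)
    attr(dense_append(a, x), "id"), integer(1))
  moved <- dense_delete(a, 1L)
  expect_equal(moved, unname(ids[3]))                 # id of "c" moved into slot 1
  expect_equal(unlist(a$items[1:2]), c("c", "b"))
  expect_equal(dense_get(a, ids[3]), "c")
  # deleting the last element moves nothing
  b <- dense_array()
  dense_append(b, "x")
  expect_null(dense_delete(b, 1L))
  expect_equal(length(b), 0L)
  expect_error(dense_delete(b, 1L), "out of range")
})

test_that("dense array location map survives random append/delete churn", {
  set.seed(42)
  a <- dense_array()
  shadow <- list()  # id -> value
  next_val <- 0L
  for (op in seq_len(5000)) {
    if (length(shadow) == 0L || runif(1) < 0.55) {
      next_val <- next_val + 1L
      id <- attr(dense_append(a, next_val), "id")
      shadow[[as.character(id)]] <- next_val
    } else {
      idx <- sample.int(length(a), 1L)
      id_deleted <- dense_ids(a)[idx]
      dense_delete(a, idx)
      shadow[[as.character(id_deleted)]] <- NULL
    }
  }
  expect_equal(length(a), length(shadow))
  # every live id resolves to the slot holding its record
  for (id in names(shadow))
    expect_identical(dense_get(a, as.integer(id)), shadow[[id]])
  # multiset of live records matches
  expect_setequal(unlist(a$items[seq_len(length(a))]), unlist(shadow))
})

test_that("holey array reuses freed slots LIFO and keeps ids stable", {
  h <- holey_array()
  s <- vapply(c("x", "y", "z"), function(v) holey_insert(h, v), integer(1))
  expect_equal(unname(s), 1:3)
  holey_free(h, 2L)
  expect_equal(holey_insert(h, "w"), 2L)      # hole reused before growing
  expect_equal(holey_get(h, 2L), "w")
  expect_equal(holey_get(h, 3L), "z")         # ids stable across churn
  expect_error(holey_free(h, 99L), "not a live slot")
  holey_free(h, 2L)
  expect_error(holey_free(h, 2L), "not a live slot")  # double free
})

test_that("holey array occupied index matches a shadow model under churn", {
  set.seed(7)
  h <- holey_array()
  live <- new.env(parent = emptyenv())
  for (op in seq_len(3000)) {
    slots <- holey_slots(h)
    if (length(slots) == 0L || runif(1) < 0.55) {
      s <- holey_insert(h, op)
      assign(as.character(s), op, envir = live)
    } else {
      s <- slots[sample.int(length(slots), 1L)]
      holey_free(h, s)
      rm(list = as.character(s), envir = live)
    }
  }
  expect_setequal(holey_slots(h), as.integer(ls(live)))
  for (s in holey_slots(h))
    expect_identical(holey_get(h, s), get(as.character(s), envir = live))
})

test_that("reaction list picks live events uniformly at random", {
  rl <- reaction_list()
  for (k in 1:4) rl_add(rl, educts = c(k, 100 + k), data = k)
  set.seed(11)
  n_draw <- 2e4
  draws <- vapply(seq_len(n_draw), function(i) rl_get(rl, rl_pick_random(rl)),
                  numeric(1))
  counts <- tabulate(draws, 4)
  # chi-square against uniform; 3 sigma on each cell as a sanity band
  chi <- sum((counts - n_draw / 4)^2 / (n_draw / 4))
  expect_lt(chi, qchisq(1 - 1e-4, df = 3))
  sigma <- sqrt(n_draw * 0.25 * 0.75)
  expect_true(all(abs(counts - n_draw / 4) < 3.9 * sigma))
  expect_error(rl_pick_random(reaction_list()), "empty")
})

test_that("clearing one educt removes exactly its events", {
  rl <- reaction_list()
  e1 <- rl_add(rl, c(1, 2), "a")    # molecule pair
  e2 <- rl_add(rl, c(1, 3), "b")
  e3 <- rl_add(rl, c(2, 3), "c")
  e4 <- rl_add(rl, c(4, 1025, 2049), "d")  # molecule + two particle keys
  rl_clear_educt(rl, 1)
  expect_setequal(rl_events(rl), c(e3, e4))
  # chains of other educts stay intact: removing educt 3 still finds e3
  rl_clear_educt(rl, 3)
  expect_setequal(rl_events(rl), e4)
  rl_clear_educt(rl, 2049)
  expect_equal(length(rl), 0L)
})

test_that("reaction list supports add/remove churn with 4-way educt chains", {
  set.seed(3)
  rl <- reaction_list()
  live <- list()
  for (op in seq_len(1500)) {
    if (length(live) == 0L || runif(1) < 0.5) {
      ed <- sample(1:12, sample(1:4, 1))
      ev <- rl_add(rl, ed, op)
      live[[as.character(ev)]] <- ed
    } else if (runif(1) < 0.6) {
      ev <- sample(names(live), 1)
      rl_remove(rl, as.integer(ev))
      live[[ev]] <- NULL
    } else {
      d <- sample(1:12, 1)
      rl_clear_educt(rl, d)
      live <- Filter(function(ed) !d %in% ed, live)
    }
  }
  expect_setequal(rl_events(rl), as.integer(names(live)))
  for (ev in names(live))
    expect_setequal(rl_educts(rl, as.integer(ev)), live[[ev]])
})
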