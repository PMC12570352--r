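# Dynamic-array containers used to track molecules, particles and the
# per-step reaction event list under constant insertion/deletion churn.

GROWTH_FACTOR <- 2L

#' Create a tightly packed dynamic array
#'
#' A contiguous container with amortised O(1) append and O(1) deletion by a
#' pop-and-swap mechanism: deleting an element moves the last element into
#' the hole, so the live region `1..length` stays contiguous.  Every element
#' receives a stable external id (monotonically issued, never reused) and a
#' location map resolves ids to current indices even as elements move.
#'
#' @param capacity initial number of allocated slots.
#' @return an object of class `dense_array`.
#' @seealso [dense_append()], [dense_delete()], [dense_get()]
#' @export
dense_array <- function(capacity = 8L) {
  arr <- new.env(parent = emptyenv())
  arr$items <- vector("list", capacity)
  arr$len <- 0L
  arr$cap <- as.integer(capacity)
  arr$ids <- integer(capacity)       # external id stored at each index
  arr$index_of <- integer(0)         # id -> index (0 = dead), grown on demand
  arr$next_id <- 1L
  class(arr) <- "dense_array"
  arr
}

#' @export
length.dense_array <- function(x) x$len

#' @export
print.dense_array <- function(x, ...) {
  cat(sprintf("<dense_array> length %d, capacity %d\n", x$len, x$cap))
  invisible(x)
}

#' Append an element to a dense array
#'
#' @param arr a [dense_array()].
#' @param item any R object.
#' @return the index the element was stored at; the issued external id is
#'   attached as attribute `"id"`.
#' @export
dense_append <- function(arr, item) {
  if (arr$len == arr$cap) {
    newcap <- max(1L, arr$cap) * GROWTH_FACTOR
    items <- vector("list", newcap)
    items[seq_len(arr$len)] <- arr$items[seq_len(arr$len)]
    arr$items <- items
    arr$ids <- c(arr$ids, integer(newcap - arr$cap))
    arr$cap <- newcap
  }
  i <- arr$len + 1L
  id <- arr$next_id
  arr$next_id <- id + 1L
  arr$items[[i]] <- item
  arr$ids[i] <- id
  if (id > length(arr$index_of)) {
    arr$index_of <- c(arr$index_of, integer(max(id, 2L * length(arr$index_of)) -
                                              length(arr$index_of)))
  }
  arr$index_of[id] <- i
  arr$len <- i
  structure(i, id = id)
}

#' Delete an element from a dense array by index (pop and swap)
#'
#' The last live element is swapped into the vacated index so the array stays
#' contiguous.
#'
#' @param arr a [dense_array()].
#' @param index index of the element to delete (must be `<= length(arr)`).
#' @return the external id of the element whose index changed, or `NULL` when
#'   the last element was deleted (nothing moved).
#' @export
dense_delete <- function(arr, index) {
  index <- as.integer(index)
  if (index < 1L || index > arr$len)
    stop("dense_delete: index ", index, " out of range [1, ", arr$len, "]")
  arr$index_of[arr$ids[index]] <- 0L
  last <- arr$len
  moved <- NULL
  if (index != last) {
    arr$items[[index]] <- arr$items[[last]]
    mid <- arr$ids[last]
    arr$ids[index] <- mid
    arr$index_of[mid] <- index
    moved <- mid
  }
  arr$items[last] <- list(NULL)
  arr$ids[last] <- 0L
  arr$len <- last - 1L
  moved
}

#' Look up elements of a dense array
#'
#' @param arr a [dense_array()].
#' @param id external id issued by [dense_append()].
#' @return `dense_get`: the stored element; `dense_index_of`: its current
#'   index (0 if dead); `dense_ids`: ids of all live elements in index order.
#' @export
dense_get <- function(arr, id) arr$items[[dense_index_of(arr, id)]]

#' @rdname dense_get
#' @export
dense_index_of <- function(arr, id) {
  if (id < 1L || id > length(arr$index_of) || arr$index_of[id] == 0L)
    stop("dense_index_of: id ", id, " is not live")
  arr$index_of[id]
}

#' @rdname dense_get
#' @export
dense_ids <- function(arr) arr$ids[seq_len(arr$len)]

# ---------------------------------------------------------------------------

#' Create a dynamic array with holes
#'
#' A slot container whose slot ids are stable for the whole lifetime of a
#' record: deletion leaves a hole that is pushed on a LIFO free list and
#' reused by the next insertion before the array grows.  A tightly packed
#' index of occupied slots is maintained alongside for fast iteration and
#' uniform random selection.
#'
#' @param capacity initial number of allocated slots.
#' @return an object of class `holey_array`.
#' @export
holey_array <- function(capacity = 8L) {
  arr <- new.env(parent = emptyenv())
  arr$slots <- vector("list", capacity)
  arr$live <- logical(capacity)
  arr$next_free <- integer(capacity)  # linked through hole slots, 0 terminates
  arr$free_head <- 0L
  arr$top <- 0L                       # highest slot ever used
  arr$cap <- as.integer(capacity)
  arr$occupied <- dense_array()       # dense list of live slot ids
  arr$occ_id <- integer(capacity)     # slot -> external id in `occupied`
  class(arr) <- "holey_array"
  arr
}

#' @export
length.holey_array <- function(x) length(x$occupied)

#' @export
print.holey_array <- function(x, ...) {
  cat(sprintf("<holey_array> %d live slots, capacity %d\n",
              length(x$occupied), x$cap))
  invisible(x)
}

#' Insert an element into a holey array
#'
#' Reuses the most recently freed slot when one exists, otherwise grows the
#' array by a multiplicative factor.
#'
#' @param arr a [holey_array()].
#' @param item any R object.
#' @return the slot id, stable until the record is freed.
#' @export
holey_insert <- function(arr, item) {
  if (arr$free_head > 0L) {
    s <- arr$free_head
    arr$free_head <- arr$next_free[s]
  } else {
    if (arr$top == arr$cap) {
      newcap <- max(1L, arr$cap) * GROWTH_FACTOR
      slots <- vector("list", newcap)
      slots[seq_len(arr$top)] <- arr$slots[seq_len(arr$top)]
      arr$slots <- slots
      arr$live <- c(arr$live, logical(newcap - arr$cap))
      arr$next_free <- c(arr$next_free, integer(newcap - arr$cap))
      arr$occ_id <- c(arr$occ_id, integer(newcap - arr$cap))
      arr$cap <- newcap
    }
    s <- arr$top + 1L
    arr$top <- s
  }
  arr$slots[[s]] <- item
  arr$live[s] <- TRUE
  arr$occ_id[s] <- attr(dense_append(arr$occupied, s), "id")
  s
}

#' Free a slot of a holey array
#'
#' @param arr a [holey_array()].
#' @param slot_id slot id returned by [holey_insert()]; freeing a hole is an
#'   error.
#' @return invisibly, the freed slot id.
#' @export
holey_free <- function(arr, slot_id) {
  s <- as.integer(slot_id)
  if (s < 1L || s > arr$top || !arr$live[s])
    stop("holey_free: slot ", s, " is not a live slot")
  arr$live[s] <- FALSE
  arr$slots[s] <- list(NULL)
  arr$next_free[s] <- arr$free_head
  arr$free_head <- s
  dense_delete(arr$occupied, dense_index_of(arr$occupied, arr$occ_id[s]))
  invisible(s)
}

#' @rdname holey_insert
#' @export
holey_get <- function(arr, slot_id) {
  s <- as.integer(slot_id)
  if (s < 1L || s > arr$top || !arr$live[s])
    stop("holey_get: slot ", s, " is not a live slot")
  arr$slots[[s]]
}

#' @rdname holey_insert
#' @export
holey_slots <- function(arr) {
  n <- length(arr$occupied)
  vapply(seq_len(n), function(i) arr$occupied$items[[i]], integer(1))
}

# ---------------------------------------------------------------------------
# Reaction event list: a doubly linked list embedded into a holey array.
# Every event carries up to 4 educt keys (two molecule ids and two particle
# ids); for each educt slot the event stores a (next event, next educt slot)
# and (prev event, prev educt slot) pointer pair, so all events of one educt
# form a chain whose head lives in a hash table.  A dense array of live event
# ids allows unbiased uniform random selection.

N_EDUCT_SLOTS <- 4L

#' Create a reaction event list
#'
#' Holds candidate reaction events of one integration step.  Supports O(1)
#' insertion, O(1) removal, removal of every event sharing a given educt, and
#' unbiased uniform random selection.
#'
#' @return an object of class `reaction_list`.
#' @export
reaction_list <- function() {
  rl <- new.env(parent = emptyenv())
  rl$ha <- holey_array(16L)
  cap <- rl$ha$cap
  rl$educts <- matrix(0, cap, N_EDUCT_SLOTS)       # 0 = unused slot
  rl$nxt_ev <- matrix(0L, cap, N_EDUCT_SLOTS)
  rl$nxt_sl <- matrix(0L, cap, N_EDUCT_SLOTS)
  rl$prv_ev <- matrix(0L, cap, N_EDUCT_SLOTS)
  rl$prv_sl <- matrix(0L, cap, N_EDUCT_SLOTS)
  rl$head <- new.env(parent = emptyenv())          # educt key -> c(ev, slot)
  rl$dense <- dense_array()                        # live event ids
  rl$dense_id <- integer(cap)                      # event -> id in `dense`
  class(rl) <- "reaction_list"
  rl
}

#' @export
length.reaction_list <- function(x) length(x$dense)

#' @export
print.reaction_list <- function(x, ...) {
  cat(sprintf("<reaction_list> %d live events\n", length(x$dense)))
  invisible(x)
}

rl_grow_to <- function(rl, cap) {
  old <- nrow(rl$educts)
  if (cap <= old) return(invisible())
  pad <- function(m, mode) rbind(m, matrix(vector(mode, (cap - old) * N_EDUCT_SLOTS),
                                           cap - old, N_EDUCT_SLOTS))
  rl$educts <- pad(rl$educts, "numeric")
  rl$nxt_ev <- pad(rl$nxt_ev, "integer")
  rl$nxt_sl <- pad(rl$nxt_sl, "integer")
  rl$prv_ev <- pad(rl$prv_ev, "integer")
  rl$prv_sl <- pad(rl$prv_sl, "integer")
  rl$dense_id <- c(rl$dense_id, integer(cap - old))
  invisible()
}

#' Add a reaction event
#'
#' @param rl a [reaction_list()].
#' @param educts numeric vector of 1 to 4 educt keys (molecule/particle ids).
#' @param data arbitrary payload describing the reaction.
#' @return the event id.
#' @export
rl_add <- function(rl, educts, data = NULL) {
  stopifnot(length(educts) >= 1L, length(educts) <= N_EDUCT_SLOTS)
  ev <- holey_insert(rl$ha, data)
  rl_grow_to(rl, rl$ha$cap)
  rl$dense_id[ev] <- attr(dense_append(rl$dense, ev), "id")
  rl$educts[ev, ] <- 0
  for (j in seq_along(educts)) {
    d <- educts[j]
    rl$educts[ev, j] <- d
    key <- as.character(d)
    h <- rl$head[[key]]
    if (is.null(h)) {
      rl$nxt_ev[ev, j] <- 0L
      rl$nxt_sl[ev, j] <- 0L
    } else {
      rl$nxt_ev[ev, j] <- h[1L]
      rl$nxt_sl[ev, j] <- h[2L]
      rl$prv_ev[h[1L], h[2L]] <- ev
      rl$prv_sl[h[1L], h[2L]] <- j
    }
    rl$prv_ev[ev, j] <- 0L
    rl$head[[key]] <- c(ev, j)
  }
  ev
}

rl_unlink_slot <- function(rl, ev, j) {
  d <- rl$educts[ev, j]
  if (d == 0) return(invisible())
  pe <- rl$prv_ev[ev, j]; ps <- rl$prv_sl[ev, j]
  ne <- rl$nxt_ev[ev, j]; ns <- rl$nxt_sl[ev, j]
  if (pe == 0L) {
    key <- as.character(d)
    if (ne == 0L) rm(list = key, envir = rl$head) else rl$head[[key]] <- c(ne, ns)
  } else {
    rl$nxt_ev[pe, ps] <- ne
    rl$nxt_sl[pe, ps] <- ns
  }
  if (ne != 0L) {
    rl$prv_ev[ne, ns] <- pe
    rl$prv_sl[ne, ns] <- ps
  }
  invisible()
}

#' Remove one reaction event
#'
#' @param rl a [reaction_list()].
#' @param ev event id returned by [rl_add()].
#' @export
rl_remove <- function(rl, ev) {
  for (j in seq_len(N_EDUCT_SLOTS)) rl_unlink_slot(rl, ev, j)
  rl$educts[ev, ] <- 0
  dense_delete(rl$dense, dense_index_of(rl$dense, rl$dense_id[ev]))
  holey_free(rl$ha, ev)
  invisible()
}

#' Remove every event containing a given educt
#'
#' Events of other educts are left intact.
#'
#' @param rl a [reaction_list()].
#' @param educt educt key.
#' @return invisibly, the removed event ids.
#' @export
rl_clear_educt <- function(rl, educt) {
  key <- as.character(educt)
  removed <- integer(0)
  repeat {
    h <- rl$head[[key]]
    if (is.null(h)) break
    rl_remove(rl, h[1L])
    removed <- c(removed, h[1L])
  }
  invisible(removed)
}

#' Pick a live reaction event uniformly at random
#'
#' @param rl a [reaction_list()].
#' @return the event id.
#' @export
rl_pick_random <- function(rl) {
  n <- length(rl$dense)
  if (n == 0L) stop("rl_pick_random: reaction list is empty")
  rl$dense$items[[sample.int(n, 1L)]]
}

#' @rdname rl_add
#' @export
rl_get <- function(rl, ev) holey_get(rl$ha, ev)

#' @rdname rl_add
#' @export
rl_educts <- function(rl, ev) {
  e <- rl$educts[ev, ]
  e[e != 0]
}

#' @rdname rl_add
#' @export
rl_events <- function(rl) {
  n <- length(rl$dense)
  vapply(seq_len(n), function(i) rl$dense$items[[i]], integer(1))
}
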