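#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// mask is a logical matrix (column-major); connectivity is 4 or 8.
// Labels are renumbered 1..K in order of first appearance in column-major scan.

static int uf_find(std::vector<int>& parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
    if (connectivity != 4 && connectivity != 8)
        stop("connectivity must be 4 or 8");
    int nr = mask.nrow(), nc = mask.ncol();
    IntegerMatrix lab(nr, nc);
    std::vector<int> parent;
    parent.push_back(0); // provisional label 0 unused

    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            if (!mask(r, c)) continue;
            int best = 0;
            // neighbours already scanned: above, left column (left, and two
            // diagonals for 8-connectivity)
            int cand[4] = {0, 0, 0, 0};
            int ncand = 0;
            if (r > 0 && mask(r - 1, c)) cand[ncand++] = lab(r - 1, c);
            if (c > 0) {
                if (mask(r, c - 1)) cand[ncand++] = lab(r, c - 1);
                if (connectivity == 8) {
                    if (r > 0 && mask(r - 1, c - 1)) cand[ncand++] = lab(r - 1, c - 1);
                    if (r < nr - 1 && mask(r + 1, c - 1)) cand[ncand++] = lab(r + 1, c - 1);
                }
            }
            for (int k = 0; k < ncand; ++k)
                if (best == 0 || cand[k] < best) best = cand[k];
            if (best == 0) {
                int lbl = (int) parent.size();
                parent.push_back(lbl);
                lab(r, c) = lbl;
            } else {
                lab(r, c) = best;
                for (int k = 0; k < ncand; ++k)
                    if (cand[k] != best) uf_union(parent, cand[k], best);
            }
        }
    }

    // second pass: resolve to roots, renumber contiguously by first appearance
    std::vector<int> remap(parent.size(), 0);
    int next = 0;
    for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
            int l = lab(r, c);
            if (l == 0) continue;
            int root = uf_find(parent, l);
            if (remap[root] == 0) remap[root] = ++next;
            lab(r, c) = remap[root];
        }
    }
    return lab;
}
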