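#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Persistence pairing by standard column reduction of the Z2 boundary
// matrix in filtration order.
//
// `boundary` holds, for the j-th cell of the filtration, the 1-based
// filtration indices of its facets, sorted ascending (vertices: empty).
// A column is reduced by repeatedly adding (symmetric difference mod 2)
// the stored column owning its lowest entry. A column that empties marks
// its cell as a creator; otherwise the cell destroys the class created by
// the cell at its final lowest entry.
//
// Returns creator/destroyer index pairs and the indices of essential
// creators (classes alive at the end of the filtration).
// [[Rcpp::export]]
List reduce_filtration(const List& boundary) {
    const int n = boundary.size();
    std::vector<std::vector<int> > cols(n);
    std::vector<int> pivot_owner(n + 1, -1);
    std::vector<char> is_paired_creator(n, 0), is_destroyer(n, 0);
    std::vector<int> cr, de, tmp;

    for (int j = 0; j < n; ++j) {
        IntegerVector b = boundary[j];
        std::vector<int> col(b.begin(), b.end());
        while (!col.empty()) {
            const int low = col.back();
            const int owner = pivot_owner[low];
            if (owner < 0) break;
            tmp.clear();
            std::set_symmetric_difference(col.begin(), col.end(),
                                          cols[owner].begin(),
                                          cols[owner].end(),
                                          std::back_inserter(tmp));
            col.swap(tmp);
        }
        if (!col.empty()) {
            const int low = col.back();
            pivot_owner[low] = j;
            cols[j] = col;
            is_destroyer[j] = 1;
            is_paired_creator[low - 1] = 1;
            cr.push_back(low);       // 1-based creator index
            de.push_back(j + 1);     // 1-based destroyer index
        }
    }

    std::vector<int> essential;
    for (int j = 0; j < n; ++j)
        if (!is_destroyer[j] && !is_paired_creator[j])
            essential.push_back(j + 1);

    return List::create(_["creator"] = wrap(cr),
                        _["destroyer"] = wrap(de),
                        _["essential"] = wrap(essential));
}
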