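#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adjacency lists from a 0/1 symmetric matrix (diagonal ignored).
// Column-major scan; symmetry makes nb[j] the neighbours of j.
static std::vector< std::vector<int> > adj_lists(const IntegerMatrix &adj) {
    int n = adj.nrow();
    std::vector< std::vector<int> > nb(n);
    for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i)
            if (i != j && adj(i, j) != 0) nb[j].push_back(i);
    return nb;
}

// All-pairs shortest-path lengths by BFS; -1 marks unreachable pairs.
// Flat-array queues: these kernels run inside permutation loops.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(IntegerMatrix adj) {
    int n = adj.nrow();
    std::vector< std::vector<int> > nb = adj_lists(adj);
    IntegerMatrix D(n, n);
    std::vector<int> dist(n), q(n);
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), -1);
        dist[s] = 0;
        int head = 0, tail = 0;
        q[tail++] = s;
        while (head < tail) {
            int u = q[head++];
            const std::vector<int> &nu = nb[u];
            for (size_t k = 0; k < nu.size(); ++k) {
                int v = nu[k];
                if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
            }
        }
        for (int j = 0; j < n; ++j) D(j, s) = dist[j];
    }
    return D;
}

// Brandes betweenness on an unweighted undirected graph; each unordered
// pair of endpoints contributes once (ordered-pair sums halved).
// [[Rcpp::export]]
NumericVector betweenness_cpp(IntegerMatrix adj) {
    int n = adj.nrow();
    std::vector< std::vector<int> > nb = adj_lists(adj);
    NumericVector bc(n);
    std::vector<int> dist(n), order(n);
    std::vector<double> sigma(n), delta(n);
    std::vector< std::vector<int> > pred(n);
    for (int s = 0; s < n; ++s) {
        for (int i = 0; i < n; ++i) { pred[i].clear(); dist[i] = -1; sigma[i] = 0.0; delta[i] = 0.0; }
        dist[s] = 0; sigma[s] = 1.0;
        int head = 0, tail = 0;
        order[tail++] = s;
        while (head < tail) {
            int u = order[head++];
            const std::vector<int> &nu = nb[u];
            for (size_t k = 0; k < nu.size(); ++k) {
                int v = nu[k];
                if (dist[v] < 0) { dist[v] = dist[u] + 1; order[tail++] = v; }
                if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
            }
        }
        // visit in reverse BFS order (non-increasing distance)
        for (int t = tail - 1; t >= 0; --t) {
            int w = order[t];
            const std::vector<int> &pw = pred[w];
            for (size_t k = 0; k < pw.size(); ++k) {
                int u = pw[k];
                delta[u] += (sigma[u] / sigma[w]) * (1.0 + delta[w]);
            }
            if (w != s) bc[w] += delta[w];
        }
    }
    for (int i = 0; i < n; ++i) bc[i] /= 2.0;
    return bc;
}

// Per-node local efficiency: global efficiency of the subgraph induced by
// each node's neighbours; nodes with fewer than 2 neighbours score 0.
// [[Rcpp::export]]
NumericVector local_efficiency_nodes_cpp(IntegerMatrix adj) {
    int n = adj.nrow();
    std::vector< std::vector<int> > nb = adj_lists(adj);
    NumericVector el(n);
    std::vector<int> idx(n, -1);
    for (int i = 0; i < n; ++i) {
        int k = (int)nb[i].size();
        if (k < 2) { el[i] = 0.0; continue; }
        // induced subgraph on the neighbours of i
        for (int a = 0; a < k; ++a) idx[nb[i][a]] = a;
        std::vector< std::vector<int> > sub(k);
        for (int a = 0; a < k; ++a) {
            int u = nb[i][a];
            for (size_t t = 0; t < nb[u].size(); ++t) {
                int v = nb[u][t];
                if (idx[v] >= 0) sub[a].push_back(idx[v]);
            }
        }
        double acc = 0.0;
        std::vector<int> dist(k), q(k);
        for (int s = 0; s < k; ++s) {
            std::fill(dist.begin(), dist.end(), -1);
            dist[s] = 0;
            int head = 0, tail = 0;
            q[tail++] = s;
            while (head < tail) {
                int u = q[head++];
                for (size_t t = 0; t < sub[u].size(); ++t) {
                    int v = sub[u][t];
                    if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
                }
            }
            for (int t = s + 1; t < k; ++t)
                if (dist[t] > 0) acc += 1.0 / dist[t];
        }
        el[i] = acc / (k * (k - 1) / 2.0);
        for (int a = 0; a < k; ++a) idx[nb[i][a]] = -1;
    }
    return el;
}

// Union-find: number of edges consumed, scanning (ei, ej) in the given
// order, at the moment the n-node graph first becomes connected; -1 if
// the full list never connects it. Indices are 0-based.
// [[Rcpp::export]]
int edges_until_connected_cpp(IntegerVector ei, IntegerVector ej, int n) {
    std::vector<int> parent(n), rank_(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
    int comps = n;
    int m = ei.size();
    for (int e = 0; e < m; ++e) {
        int a = ei[e], b = ej[e];
        while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
        while (parent[b] != b) { parent[b] = parent[parent[b]]; b = parent[b]; }
        if (a != b) {
            if (rank_[a] < rank_[b]) std::swap(a, b);
            parent[b] = a;
            if (rank_[a] == rank_[b]) rank_[a]++;
            if (--comps == 1) return e + 1;
        }
    }
    return (n <= 1) ? 0 : -1;
}

// Size of the largest connected component (singletons count as size 1).
// [[Rcpp::export]]
int lcc_size_cpp(IntegerMatrix adj) {
    int n = adj.nrow();
    if (n == 0) return 0;
    std::vector< std::vector<int> > nb = adj_lists(adj);
    std::vector<int> seen(n, 0), q(n);
    int best = 0;
    for (int s = 0; s < n; ++s) {
        if (seen[s]) continue;
        int head = 0, tail = 0;
        q[tail++] = s; seen[s] = 1;
        while (head < tail) {
            int u = q[head++];
            for (size_t k = 0; k < nb[u].size(); ++k) {
                int v = nb[u][k];
                if (!seen[v]) { seen[v] = 1; q[tail++] = v; }
            }
        }
        if (tail > best) best = tail;
    }
    return best;
}
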