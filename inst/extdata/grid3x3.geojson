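{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"edge_id":"s01"},"geometry":{"type":"LineString","coordinates":[[0,0],[100,0]]}},{"type":"Feature","properties":{"edge_id":"s02"},"geometry":{"type":"LineString","coordinates":[[0,0],[0,100]]}},{"type":"Feature","properties":{"edge_id":"s03"},"geometry":{"type":"LineString","coordinates":[[100,0],[200,0]]}},{"type":"Feature","properties":{"edge_id":"s04"},"geometry":{"type":"LineString","coordinates":[[100,0],[100,100]]}},{"type":"Feature","properties":{"edge_id":"s05"},"geometry":{"type":"LineString","coordinates":[[200,0],[200,100]]}},{"type":"Feature","properties":{"edge_id":"s06"},"geometry":{"type":"LineString","coordinates":[[0,100],[100,100]]}},{"type":"Feature","properties":{"edge_id":"s07"},"geometry":{"type":"LineString","coordinates":[[0,100],[0,200]]}},{"type":"Feature","properties":{"edge_id":"s08"},"geometry":{"type":"LineString","coordinates":[[100,100],[200,100]]}},{"type":"Feature","properties":{"edge_id":"s09"},"geometry":{"type":"LineString","coordinates":[[100,100],[100,200]]}},{"type":"Feature","properties":{"edge_id":"s10"},"geometry":{"type":"LineString","coordinates":[[200,100],[200,200]]}},{"type":"Feature","properties":{"edge_id":"s11"},"geometry":{"type":"LineString","coordinates":[[0,200],[100,200]]}},{"type":"Feature","properties":{"edge_id":"s12"},"geometry":{"type":"LineString","coordinates":[[100,200],[200,200]]}}]}
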