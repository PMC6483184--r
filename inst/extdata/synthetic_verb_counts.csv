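speaker_id,year,tokens,novel
s001,1993,20,2
s002,1993,20,6
s003,1993,20,0
s004,1993,20,4
s005,1993,20,2
s006,1993,20,2
s007,1993,20,8
s008,1993,20,0
s009,1993,20,0
s010,1993,20,0
s011,1993,20,1
s012,1993,20,3
s013,1993,20,0
s014,1993,20,2
s015,1993,20,0
s016,1993,20,4
s017,1993,20,0
s018,1993,20,3
s019,1993,20,3
s020,1993,20,0
s021,1993,20,1
s022,1993,20,0
s023,1993,20,5
s024,1993,20,7
s025,1993,20,0
s001,2007,20,3
s002,2007,20,7
s003,2007,20,0
s004,2007,20,10
s005,2007,20,6
s006,2007,20,0
s007,2007,20,7
s008,2007,20,4
s009,2007,20,5
s010,2007,20,0
s011,2007,20,6
s012,2007,20,2
s013,2007,20,0
s014,2007,20,1
s015,2007,20,6
s016,2007,20,2
s017,2007,20,9
s018,2007,20,1
s019,2007,20,2
s020,2007,20,1
s021,2007,20,3
s022,2007,20,4
s023,2007,20,3
s024,2007,20,7
s025,2007,20,11
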