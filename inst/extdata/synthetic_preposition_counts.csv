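speaker_id,year,tokens,novel
s001,1993,20,0
s002,1993,20,2
s003,1993,20,0
s004,1993,20,2
s005,1993,20,0
s006,1993,20,1
s007,1993,20,12
s008,1993,20,0
s009,1993,20,1
s010,1993,20,1
s011,1993,20,6
s012,1993,20,5
s013,1993,20,3
s014,1993,20,3
s015,1993,20,6
s016,1993,20,3
s017,1993,20,1
s018,1993,20,6
s019,1993,20,6
s020,1993,20,6
s021,1993,20,3
s022,1993,20,0
s023,1993,20,1
s024,1993,20,4
s025,1993,20,2
s026,1993,20,9
s027,1993,20,5
s028,1993,20,4
s029,1993,20,0
s030,1993,20,0
s031,1993,20,3
s032,1993,20,7
s033,1993,20,3
s034,1993,20,2
s035,1993,20,3
s036,1993,20,0
s037,1993,20,6
s038,1993,20,6
s039,1993,20,4
s040,1993,20,1
s041,1993,20,2
s042,1993,20,2
s043,1993,20,10
s044,1993,20,6
s045,1993,20,2
s046,1993,20,9
s047,1993,20,1
s048,1993,20,2
s049,1993,20,4
s050,1993,20,4
s001,2007,20,6
s002,2007,20,6
s003,2007,20,8
s004,2007,20,7
s005,2007,20,6
s006,2007,20,5
s007,2007,20,10
s008,2007,20,5
s009,2007,20,1
s010,2007,20,2
s011,2007,20,6
s012,2007,20,5
s013,2007,20,4
s014,2007,20,4
s015,2007,20,12
s016,2007,20,2
s017,2007,20,2
s018,2007,20,5
s019,2007,20,2
s020,2007,20,4
s021,2007,20,4
s022,2007,20,1
s023,2007,20,7
s024,2007,20,2
s025,2007,20,4
s026,2007,20,8
s027,2007,20,2
s028,2007,20,7
s029,2007,20,7
s030,2007,20,1
s031,2007,20,3
s032,2007,20,3
s033,2007,20,10
s034,2007,20,8
s035,2007,20,5
s036,2007,20,2
s037,2007,20,9
s038,2007,20,7
s039,2007,20,3
s040,2007,20,10
s041,2007,20,4
s042,2007,20,1
s043,2007,20,3
s044,2007,20,3
s045,2007,20,9
s046,2007,20,8
s047,2007,20,4
s048,2007,20,9
s049,2007,20,5
s050,2007,20,6
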