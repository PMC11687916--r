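dialect,external,canonical
slam_pbp,match_id,match_id
slam_pbp,ElapsedTime,elapsed_seconds
slam_pbp,SetNo,set_no
slam_pbp,GameNo,game_no
slam_pbp,PointNumber,point_no
slam_pbp,PointServer,server
slam_pbp,PointWinner,point_victor
slam_pbp,GameWinner,game_victor
slam_pbp,SetWinner,set_victor
slam_pbp,P1Ace,ace_1
slam_pbp,P2Ace,ace_2
slam_pbp,P1Winner,winner_1
slam_pbp,P2Winner,winner_2
slam_pbp,P1DoubleFault,double_fault_1
slam_pbp,P2DoubleFault,double_fault_2
slam_pbp,P1UnfErr,unf_err_1
slam_pbp,P2UnfErr,unf_err_2
slam_pbp,P1NetPoint,net_pt_1
slam_pbp,P2NetPoint,net_pt_2
slam_pbp,P1NetPointWon,net_pt_won_1
slam_pbp,P2NetPointWon,net_pt_won_2
slam_pbp,P1BreakPoint,break_pt_1
slam_pbp,P2BreakPoint,break_pt_2
slam_pbp,P1BreakPointWon,break_pt_won_1
slam_pbp,P2BreakPointWon,break_pt_won_2
slam_pbp,P1DistanceRun,distance_run_1
slam_pbp,P2DistanceRun,distance_run_2
slam_pbp,RallyCount,rally_count
slam_pbp,Speed_KMH,serve_speed
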